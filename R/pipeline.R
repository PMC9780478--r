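#' Pipeline configuration and orchestration
#'
#' A validated configuration drives the full label-volume-to-FE-deck
#' pipeline: per-tissue reconstruction, bone remeshing, cartilage hex
#' meshing with blending, attachment-site mapping, and export.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @return named list: `tissues` (label map), `bone_target_edge_mm`,
#'   `cartilage` ([cartilage_mesh_config()]), reconstruction parameters,
#'   `seed`, `workers` (bone / cartilage pool sizes), `output_dir`.
#' @export
pipeline_config <- function() {
  list(tissues = as.list(default_tissue_map()),
       cartilage_sites = list(femoral_cartilage = "femoral",
                              tibial_cartilage_medial = "tibial",
                              tibial_cartilage_lateral = "tibial",
                              patellar_cartilage = "patellar"),
       cartilage_bones = list(femoral_cartilage = "femur",
                              tibial_cartilage_medial = "tibia",
                              tibial_cartilage_lateral = "tibia",
                              patellar_cartilage = "patella"),
       bone_target_edge_mm = 3.0,
       decimation_fraction = 0.8,
       smoothing_iterations = 9L,
       cartilage = cartilage_mesh_config(),
       seed = 1L,
       workers = list(bone = 3L, cartilage = 4L),
       output_dir = ".")
}

#' Validate a pipeline configuration against the schema
#'
#' Unknown keys (at the top level and within the `cartilage` and `workers`
#' blocks) are rejected; values are type-checked against the defaults.
#'
#' @param config a (possibly partial) configuration list.
#' @return the merged, validated configuration.
#' @export
validate_config <- function(config = list()) {
  ref <- pipeline_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (blk in c("cartilage", "workers")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(ref[[blk]]))
      if (length(bad))
        stop("unknown keys in '", blk, "': ", paste(bad, collapse = ", "))
    }
  }
  merged <- modifyList(ref, config)
  stopifnot(merged$bone_target_edge_mm > 0,
            merged$decimation_fraction >= 0, merged$decimation_fraction < 1,
            merged$smoothing_iterations >= 0,
            merged$cartilage$target_edge_mm > 0,
            merged$cartilage$depth_layers >= 1)
  merged
}

#' Read a pipeline configuration from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("config must be YAML or JSON"))
  validate_config(cfg)
}

#' Run the full meshing pipeline
#'
#' Reconstructs every tissue present in the label volume, remeshes bones,
#' hex-meshes cartilage tissues (with blending and bone fusion against the
#' mapped bone), maps template attachment sites if an atlas is given, and
#' writes meshes, provenance and an FE deck to the output directory.
#' Per-tissue failures are isolated: the bundle reports partial success.
#'
#' @param labels a [label_volume()], a `phantom`, or a path to a NIfTI
#'   label volume.
#' @param config configuration (see [pipeline_config()]); validated before
#'   any stage runs.
#' @param atlas optional `template_atlas` for attachment-site mapping.
#' @param write_outputs write mesh/provenance files to
#'   `config$output_dir` (set `FALSE` to keep results in memory only).
#' @return an `output_bundle`: per-tissue meshes, provenance (fallbacks,
#'   timings, quality summaries), attachment sites, failures, and the
#'   configuration hash and seed.
#' @export
run_pipeline <- function(labels, config = list(), atlas = NULL,
                         write_outputs = FALSE) {
  config <- validate_config(if (is.list(config) &&
                                is.null(config$tissues)) config else config)
  volume <- if (inherits(labels, "phantom")) labels$label_volume
  else if (inherits(labels, "label_volume")) labels
  else read_label_volume(labels)

  present <- unique(as.vector(volume$codes))
  tmap <- unlist(config$tissues)
  tmap <- tmap[tmap %in% present]
  # phantom label volumes carry their own map
  if (!is.null(volume$tissue_map)) {
    tmap <- volume$tissue_map[volume$tissue_map %in% present]
  }
  bones <- names(tmap)[grepl("bone|femur|tibia|patella", names(tmap)) &
                         !grepl("cartilage", names(tmap))]
  carts <- names(tmap)[grepl("cartilage", names(tmap))]

  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }
  run_tissue <- function(fn, nm) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      structure(list(message = conditionMessage(e)), class = "tissue_error"))
    list(result = res,
         seconds = as.numeric(Sys.time() - t0, units = "secs"))
  }
  pool_map <- function(names_vec, fn, workers) {
    if (workers > 1 && .Platform$OS.type == "unix") {
      res <- parallel::mclapply(names_vec, fn, mc.cores = workers)
      names(res) <- names_vec
      res
    } else {
      res <- lapply(names_vec, fn)
      names(res) <- names_vec
      res
    }
  }

  note("reconstructing %d bone + %d cartilage tissues", length(bones),
       length(carts))
  bone_meshes <- pool_map(bones, function(nm) {
    run_tissue(function() {
      surf <- reconstruct_tissue(volume, nm, "bone",
                                 config$decimation_fraction,
                                 config$smoothing_iterations)
      remesh_uniform(surf, config$bone_target_edge_mm, seed = config$seed)
    }, nm)
  }, config$workers$bone)

  cart_site <- function(nm) {
    site <- config$cartilage_sites[[nm]]
    if (is.null(site)) {
      site <- if (grepl("femoral", nm)) "femoral"
      else if (grepl("patell", nm)) "patellar" else "tibial"
    }
    site
  }
  cart_bone <- function(nm) {
    bn <- config$cartilage_bones[[nm]]
    if (!is.null(bn) && bn %in% names(bone_meshes) &&
        !inherits(bone_meshes[[bn]]$result, "tissue_error"))
      return(bone_meshes[[bn]]$result)
    if (length(bones) == 1 &&
        !inherits(bone_meshes[[1]]$result, "tissue_error"))
      return(bone_meshes[[1]]$result)
    NULL
  }
  cart_meshes <- pool_map(carts, function(nm) {
    run_tissue(function() {
      surf <- reconstruct_tissue(volume, nm, "cartilage",
                                 config$decimation_fraction,
                                 config$smoothing_iterations)
      mesh_cartilage(surf, cart_site(nm), cart_bone(nm), config$cartilage)
    }, nm)
  }, config$workers$cartilage)

  sites <- NULL
  if (!is.null(atlas)) {
    femur_nm <- intersect(c("femur", "bone"), names(bone_meshes))[1]
    if (!is.na(femur_nm) &&
        !inherits(bone_meshes[[femur_nm]]$result, "tissue_error")) {
      tf <- register_icp(bone_meshes[[femur_nm]]$result, atlas$femur_surface)
      subj <- list(femur = bone_meshes[[femur_nm]]$result)
      sites <- map_attachment_sites(tf, atlas, subj)
      note("mapped %d attachment sites (ICP residual %.3f mm)",
           nrow(sites), attr(tf, "residual"))
    }
  }

  quality <- function(entry) {
    m <- entry$result
    if (inherits(m, "tissue_error") || is.null(m$hexes)) return(NULL)
    sj <- scaled_jacobian_all(m$nodes, m$hexes)
    per_layer <- tapply(sj, m$element_layer, function(x)
      c(min = min(x), mean = mean(x)))
    list(min_sj = min(sj), mean_sj = mean(sj),
         per_layer = lapply(per_layer, as.list),
         fallbacks = m$provenance$fallbacks,
         fusion = m$provenance$fusion)
  }
  provenance <- list(
    config_hash = config_hash(config), seed = config$seed,
    bones = lapply(bone_meshes, function(e) list(
      seconds = e$seconds,
      failed = inherits(e$result, "tissue_error"),
      message = if (inherits(e$result, "tissue_error")) e$result$message)),
    cartilage = lapply(cart_meshes, function(e) c(list(
      seconds = e$seconds,
      failed = inherits(e$result, "tissue_error"),
      message = if (inherits(e$result, "tissue_error")) e$result$message),
      quality(e))))

  failures <- c(
    names(bone_meshes)[vapply(bone_meshes, function(e)
      inherits(e$result, "tissue_error"), logical(1))],
    names(cart_meshes)[vapply(cart_meshes, function(e)
      inherits(e$result, "tissue_error"), logical(1))])

  bundle <- structure(list(
    bones = lapply(bone_meshes, `[[`, "result"),
    cartilage = lapply(cart_meshes, `[[`, "result"),
    attachment_sites = sites,
    provenance = provenance,
    failures = failures,
    log = log_lines), class = "output_bundle")

  if (isTRUE(write_outputs)) write_bundle(bundle, config)
  bundle
}

#' @export
print.output_bundle <- function(x, ...) {
  cat(sprintf("<output_bundle: %d bones, %d cartilage meshes%s>\n",
              length(x$bones), length(x$cartilage),
              if (length(x$failures))
                paste0("; FAILED: ", paste(x$failures, collapse = ", "))
              else ""))
  invisible(x)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)
  # small deterministic fingerprint (djb2) -- avoids a digest dependency
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

write_bundle <- function(bundle, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outdir <- config$output_dir
  meshes <- list()
  for (nm in names(bundle$bones)) {
    m <- bundle$bones[[nm]]
    if (inherits(m, "tissue_error")) next
    write_mesh(m, file.path(outdir, paste0(nm, ".stl")))
    meshes[[nm]] <- m
  }
  for (nm in names(bundle$cartilage)) {
    m <- bundle$cartilage[[nm]]
    if (inherits(m, "tissue_error")) next
    write_mesh(m, file.path(outdir, paste0(nm, ".vtu")))
    meshes[[nm]] <- m
  }
  if (length(meshes))
    export_fe_deck(meshes, bundle$attachment_sites,
                   file.path(outdir, "model.inp"))
  jsonlite::write_json(bundle$provenance,
                       file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  writeLines(bundle$log, file.path(outdir, "pipeline.log"))
  invisible(outdir)
}
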