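# Cohort and report input/output: one NIfTI volume per patient plus a CSV
# clinical table keyed by patient id, so a real cohort in the same layout can
# be swapped in for the synthetic one.

#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialisation; embedded in manifests and reports
#' for provenance.
#'
#' @param x Any jsonlite-serialisable object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE),
    tmp
  )
  unname(tools::md5sum(tmp))
}

#' Write a cohort to disk
#'
#' Emits `<patient_id>.nii.gz` per patient, a `clinical.csv` table with the
#' patient id, label and all covariates, and a `manifest.json` recording the
#' generating configuration, its seed and hash, and (for synthetic cohorts)
#' the latent truth per patient.
#'
#' @param cohort List of patient records.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  rows <- lapply(cohort, function(r) {
    c(list(patient_id = r$patient_id, label = r$label),
      r$quantitative, r$qualitative)
  })
  clin <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  for (r in cohort) {
    RNifti::writeNifti(
      RNifti::asNifti(r$volume, datatype = "double"),
      file.path(dir, paste0(r$patient_id, ".nii.gz"))
    )
  }
  cfg <- attr(cohort, "config")
  truth <- lapply(cohort, function(r) {
    list(patient_id = r$patient_id, risk = r$risk,
         lesion_radius = r$lesion$radius, lesion_contrast = r$lesion$contrast)
  })
  manifest <- list(
    n_patients = length(cohort),
    config = unclass(cfg),
    config_hash = if (!is.null(cfg)) config_hash(unclass(cfg)) else NULL,
    synthetic_truth = if (!is.null(cohort[[1]]$risk)) truth else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()] (or real data in that layout)
#'
#' Volumes are min-max scaled to `[0, 1]` when they fall outside it (real CT
#' intensities); synthetic volumes already in range are left untouched.
#'
#' @param dir Directory containing `clinical.csv` and one NIfTI per patient.
#' @return List of patient records.
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "clinical.csv")
  if (!file.exists(csv)) stop("no clinical.csv in ", dir)
  clin <- utils::read.csv(csv, stringsAsFactors = FALSE)
  quant_fields <- intersect(.QUANT_SCHEMA$field, names(clin))
  qual_fields <- intersect(names(.QUAL_SCHEMA), names(clin))
  manifest_path <- file.path(dir, "manifest.json")
  truth <- NULL
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    truth <- manifest$synthetic_truth
  }
  cohort <- lapply(seq_len(nrow(clin)), function(i) {
    pid <- clin$patient_id[i]
    vol <- as.array(RNifti::readNifti(file.path(dir, paste0(pid, ".nii.gz"))))
    rng <- range(vol)
    if (rng[1] < 0 || rng[2] > 1) {
      vol <- (vol - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    }
    rec <- list(
      patient_id = pid,
      volume = vol,
      quantitative = as.list(clin[i, quant_fields, drop = FALSE]),
      qualitative = lapply(clin[i, qual_fields, drop = FALSE], as.character),
      label = as.integer(clin$label[i])
    )
    if (!is.null(truth)) {
      j <- match(pid, truth$patient_id)
      if (!is.na(j)) {
        rec$risk <- truth$risk[j]
        rec$lesion <- list(radius = truth$lesion_radius[j],
                           contrast = truth$lesion_contrast[j])
      }
    }
    rec
  })
  cohort
}

#' Save a trained model to disk
#'
#' Single-file checkpoint with the configuration embedded; parameters and the
#' training log are serialised as JSON so checkpoints stay text-based.
#'
#' @param model A `thc_model`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- list(
    cfg = unclass(model$cfg),
    params = lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.numeric(p))
    }),
    trained = model$trained,
    clinical_stats = if (!is.null(model$clinical_stats)) {
      list(mean = as.list(model$clinical_stats$mean),
           sd = as.list(model$clinical_stats$sd))
    },
    feature_stats = if (!is.null(model$feature_stats)) {
      list(mean = model$feature_stats$mean, sd = model$feature_stats$sd)
    },
    training_log = model$training_log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Checkpoint file path.
#' @return A `thc_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, payload$cfg[
    setdiff(names(payload$cfg), character(0))
  ])
  model <- build_model(cfg)
  for (nm in names(payload$params)) {
    p <- payload$params[[nm]]
    model$params[[nm]] <- if (length(p$dim) > 1L) {
      array(p$data, dim = p$dim)
    } else {
      as.numeric(p$data)
    }
  }
  model$trained <- isTRUE(payload$trained)
  if (!is.null(payload$clinical_stats)) {
    model$clinical_stats <- structure(
      list(mean = unlist(payload$clinical_stats$mean),
           sd = unlist(payload$clinical_stats$sd)),
      class = "clinical_stats"
    )
  }
  if (!is.null(payload$feature_stats)) {
    model$feature_stats <- list(mean = as.numeric(payload$feature_stats$mean),
                                sd = as.numeric(payload$feature_stats$sd))
  }
  model$training_log <- payload$training_log
  model
}
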