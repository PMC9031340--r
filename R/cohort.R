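# Synthetic cohorts: 3-D volumes with a planted lesion signal plus clinical
# covariates in the schema used by head-neck / lung recurrence studies.

# Quantitative covariate schema: physiologically plausible location/scale and,
# for the two blood markers tied to patient condition, a linear dependence on
# the latent risk z (worse condition -> lower hemoglobin and albumin).
.QUANT_SCHEMA <- data.frame(
  field = c("hemoglobin", "lymphocytes", "leucocytes", "thrombocytes",
            "albumin", "treatment_duration", "total_dose", "n_fractions",
            "dose_per_fraction", "weight"),
  unit = c("g/dL", "Giga/L", "Giga/L", "Giga/L", "g/L", "days", "Gy", "",
           "Gy", "kg"),
  mean = c(13.5, 1.8, 7.5, 250, 40, 45, 66, 33, 2.0, 72),
  sd = c(1.2, 0.6, 2.0, 60, 4, 7, 4, 3, 0.15, 12),
  risk_slope = c(-1.0, 0, 0, 0, -2.5, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

.QUAL_SCHEMA <- list(
  gender = list(levels = c("M", "F"), probs = c(0.7, 0.3)),
  tabacology = list(levels = c("smoker", "non_smoker", "former"),
                    probs = c(0.4, 0.3, 0.3)),
  induction_chemo = list(levels = c("yes", "no"), probs = c(0.3, 0.7)),
  concomitant_chemo = list(levels = c("yes", "no"), probs = c(0.6, 0.4)),
  tnm = list(levels = c("stage_i", "stage_ii", "stage_iii", "stage_iv"),
             probs = c(0.15, 0.30, 0.35, 0.20))
)

#' Length of the encoded clinical covariate vector
#'
#' Ten z-scored quantitative fields plus one-hot blocks for the five
#' categorical fields (2 + 3 + 2 + 2 + 4 indicators).
#' @return Integer, 23 under the default schema.
#' @export
clinical_encoding_dim <- function() {
  nrow(.QUANT_SCHEMA) +
    sum(vapply(.QUAL_SCHEMA, function(s) length(s$levels), integer(1)))
}

#' Configuration of a synthetic cohort
#'
#' @param n_patients Number of patients (>= 10).
#' @param volume_shape Integer triple (H, W, D).
#' @param prevalence Target recurrence rate, strictly in (0, 1).
#' @param signal_strength Slope of the latent risk in the label model
#'   (`label ~ Bernoulli(plogis(signal_strength * z + offset))`); 0 makes the
#'   label independent of every feature.
#' @param noise_sd Standard deviation of the additive voxel noise.
#' @param seed Integer seed; cohorts are fully reproducible from it.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_patients = 200L, volume_shape = c(32L, 32L, 16L),
                          prevalence = 0.5, signal_strength = 2,
                          noise_sd = 0.02, seed = 1L) {
  if (n_patients < 10L) stop("'n_patients' must be >= 10")
  if (prevalence <= 0 || prevalence >= 1) stop("'prevalence' must be in (0, 1)")
  if (signal_strength < 0) stop("'signal_strength' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L)) {
    stop("'volume_shape' must be three dimensions of at least 8 voxels")
  }
  structure(
    list(n_patients = as.integer(n_patients), volume_shape = volume_shape,
         prevalence = prevalence, signal_strength = signal_strength,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Offset b solving E_z[plogis(s * z + b)] = prevalence for z ~ N(0, 1).
.prevalence_offset <- function(signal_strength, prevalence) {
  if (signal_strength == 0) return(stats::qlogis(prevalence))
  f <- function(b) {
    stats::integrate(
      function(z) stats::dnorm(z) * stats::plogis(signal_strength * z + b),
      -Inf, Inf
    )$value - prevalence
  }
  sol <- tryCatch(
    stats::uniroot(f, c(-60, 60), tol = 1e-10),
    error = function(e) stop("could not solve the prevalence offset: ",
                             conditionMessage(e))
  )
  sol$root
}

#' Render one synthetic volume
#'
#' The background is a fixed smooth low-intensity field plus Gaussian voxel
#' noise; one ellipsoidal lesion is placed at a uniformly random interior
#' position with radius `base_radius * (1 + 0.3 * plogis(risk))` and additive
#' intensity contrast `0.6 * plogis(risk)`. Values are clipped to `[0, 1]`.
#' Uses the current RNG stream (seed the caller for reproducibility).
#'
#' @param risk Latent risk score of the patient.
#' @param shape Integer triple (H, W, D).
#' @param noise_sd Voxel noise standard deviation.
#' @param base_radius Lesion base radius in voxels; defaults to 15% of the
#'   smallest dimension.
#' @return 3-D array in `[0, 1]` with attribute `lesion` (radius, contrast,
#'   center).
#' @export
render_volume <- function(risk, shape, noise_sd = 0.02, base_radius = NULL) {
  shape <- as.integer(shape)
  H <- shape[1]; W <- shape[2]; D <- shape[3]
  if (is.null(base_radius)) base_radius <- 0.15 * min(shape)
  radius <- base_radius * (1 + 0.3 * stats::plogis(risk))
  contrast <- 0.6 * stats::plogis(risk)
  semi <- radius * c(1, 0.85, 0.7)
  margin <- ceiling(max(semi)) + 1L
  if (any(2L * margin >= shape)) {
    stop("lesion does not fit inside the volume at this base_radius")
  }

  x <- seq_len(H); y <- seq_len(W); z <- seq_len(D)
  # fixed smooth background: gentle intensity gradient, identical across
  # patients so that lesion-driven differences are not masked
  bg <- 0.15 +
    0.05 * outer(outer(sin(2 * pi * x / H), cos(2 * pi * y / W)), z / D)
  vol <- bg + array(stats::rnorm(H * W * D, 0, noise_sd), dim = shape)

  center <- c(
    stats::runif(1, margin + 1, H - margin),
    stats::runif(1, margin + 1, W - margin),
    stats::runif(1, margin + 1, D - margin)
  )
  dx2 <- ((x - center[1]) / semi[1])^2
  dy2 <- ((y - center[2]) / semi[2])^2
  dz2 <- ((z - center[3]) / semi[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  vol <- vol + contrast * stats::plogis(6 * (1 - d2))

  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  attr(vol, "lesion") <- list(radius = radius, contrast = contrast,
                              center = center)
  vol
}

.sample_quantitative <- function(z) {
  s <- .QUANT_SCHEMA
  vals <- stats::rnorm(nrow(s), mean = s$mean + s$risk_slope * z, sd = s$sd)
  vals[s$field == "n_fractions"] <- round(vals[s$field == "n_fractions"])
  stats::setNames(as.list(vals), s$field)
}

.sample_qualitative <- function() {
  lapply(.QUAL_SCHEMA, function(sch) sample(sch$levels, 1, prob = sch$probs))
}

#' Generate a synthetic cohort with a planted label signal
#'
#' Each patient has a latent risk `z ~ N(0, 1)`. The recurrence label is
#' `Bernoulli(plogis(signal_strength * z + offset))` with the offset solved so
#' that the expected prevalence matches the configuration. Lesion radius and
#' contrast increase monotonically in `z`; hemoglobin and albumin decrease
#' linearly in `z`; the remaining covariates are label-independent noise in
#' plausible physiological ranges.
#'
#' @param cfg A [cohort_config()].
#' @return List of patient records, each with `volume`, `quantitative`,
#'   `qualitative`, `label`, `risk` and `lesion` fields; the configuration is
#'   attached as attribute `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  z <- stats::rnorm(n)
  offset <- .prevalence_offset(cfg$signal_strength, cfg$prevalence)
  p_label <- stats::plogis(cfg$signal_strength * z + offset)
  labels <- stats::rbinom(n, 1L, p_label)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- render_volume(z[i], cfg$volume_shape, cfg$noise_sd)
    lesion <- attr(vol, "lesion")
    attr(vol, "lesion") <- NULL
    cohort[[i]] <- list(
      patient_id = sprintf("P%04d", i),
      volume = vol,
      quantitative = .sample_quantitative(z[i]),
      qualitative = .sample_qualitative(),
      label = labels[i],
      risk = z[i],
      lesion = lesion
    )
  }
  attr(cohort, "config") <- cfg
  cohort
}

#' Normalisation statistics for clinical encoding
#'
#' Means and standard deviations of the quantitative fields, computed on the
#' given (training) cohort only, so that held-out patients can be encoded
#' without leakage.
#'
#' @param cohort List of patient records.
#' @return A `clinical_stats` object.
#' @export
clinical_stats <- function(cohort) {
  fields <- .QUANT_SCHEMA$field
  m <- vapply(fields, function(f) {
    mean(vapply(cohort, function(r) r$quantitative[[f]], numeric(1)))
  }, numeric(1))
  s <- vapply(fields, function(f) {
    stats::sd(vapply(cohort, function(r) r$quantitative[[f]], numeric(1)))
  }, numeric(1))
  s[!is.finite(s) | s < 1e-12] <- 1
  structure(list(mean = m, sd = s), class = "clinical_stats")
}

#' Encode one patient's clinical covariates as a numeric vector
#'
#' Quantitative fields are z-scored with the supplied (training-fold)
#' statistics; categorical fields are one-hot encoded against the fixed
#' schema level sets.
#'
#' @param record A patient record.
#' @param stats A [clinical_stats()] object.
#' @return Named numeric vector of length [clinical_encoding_dim()].
#' @export
encode_clinical <- function(record, stats) {
  stopifnot(inherits(stats, "clinical_stats"))
  fields <- .QUANT_SCHEMA$field
  quant <- vapply(fields, function(f) {
    v <- record$quantitative[[f]]
    if (is.null(v) || !is.finite(v)) stop("missing quantitative field: ", f)
    (v - stats$mean[[f]]) / stats$sd[[f]]
  }, numeric(1))
  hot <- unlist(lapply(names(.QUAL_SCHEMA), function(f) {
    lv <- .QUAL_SCHEMA[[f]]$levels
    v <- record$qualitative[[f]]
    if (is.null(v) || !(v %in% lv)) {
      stop(sprintf("unseen level '%s' in categorical field '%s'", v, f))
    }
    stats::setNames(as.numeric(lv == v), paste0(f, ".", lv))
  }))
  c(quant, hot)
}

#' Encode a whole cohort's clinical covariates
#'
#' @inheritParams encode_clinical
#' @param cohort List of patient records.
#' @return Numeric matrix, one row per patient.
#' @export
encode_cohort_clinical <- function(cohort, stats) {
  t(vapply(cohort, encode_clinical, numeric(clinical_encoding_dim()),
           stats = stats))
}
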