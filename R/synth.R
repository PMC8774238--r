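#' Configuration of the synthetic two-class cohort
#'
#' Defines the generative model of the validation cohort: images emulate
#' a low-attenuation peritumoral band (edema plateau around `base_hu`)
#' in which the HGG-like class A carries granular heterogeneity —
#' Poisson-scattered bright blobs (infiltration-like foci) on a
#' short-range correlated field — while the BM-like class B is a
#' smoother, longer-range field without blobs (pure-edema-like). These
#' ingredients reproduce the direction pattern the analysis expects:
#' higher local variation, higher gray-level non-uniformity and an
#' upward-shifted lower histogram tail in class A; energy shifted to
#' deeper wavelet scales in class B.
#'
#' @param n_per_class subjects per class; length 1 or 2 (`(A, B)`).
#' @param image_px image size `(rows, cols)`, default 128 x 128.
#' @param base_hu edema plateau attenuation (default 8 HU, realistic for
#'   vasogenic edema on CT).
#' @param noise_sd i.i.d. pixel noise SD in HU.
#' @param class_a,class_b per-class parameter lists; see Details.
#' @param rng_seed cohort seed; per-subject seeds are derived as
#'   `rng_seed + subject index`, so resizing the cohort keeps existing
#'   subjects identical.
#' @details `class_a` fields: `blob_density` (blobs per cm^2),
#'   `blob_radius_px`, `blob_amplitude_hu`, `field_amplitude` (HU),
#'   `field_corr_len_px` (Gaussian kernel length; short) and
#'   `field_type` (`"granular"`: the field is modulated by a pixel-scale
#'   alternating sign, concentrating its energy at the finest scale).
#'   `class_b` fields: `field_amplitude` (smaller), `field_corr_len_px`
#'   (longer), `field_type = "smooth"`, and implicitly
#'   `blob_density = 0`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(17L, 19L),
                          image_px = c(128L, 128L),
                          base_hu = 8, noise_sd = 1,
                          class_a = list(blob_density = 0.35,
                                         blob_radius_px = 2.5,
                                         blob_amplitude_hu = 13,
                                         field_amplitude = 4,
                                         field_corr_len_px = 1.4,
                                         field_type = "granular"),
                          class_b = list(field_amplitude = 2.8,
                                         field_corr_len_px = 2.5,
                                         field_type = "smooth"),
                          rng_seed = 1L) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  n_per_class <- as.integer(n_per_class)
  if (any(n_per_class < 0)) stop("n_per_class must be non-negative", call. = FALSE)
  stopifnot(length(image_px) == 2L, all(image_px >= 32L))
  amps <- c(class_a$blob_amplitude_hu, class_a$field_amplitude,
            class_b$field_amplitude, noise_sd)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  class_a$blob_density <- class_a$blob_density %||% 0
  class_b$blob_density <- 0
  class_a$field_type <- class_a$field_type %||% "granular"
  class_b$field_type <- class_b$field_type %||% "smooth"
  structure(list(n_per_class = n_per_class, image_px = as.integer(image_px),
                 base_hu = base_hu, noise_sd = noise_sd,
                 class_a = class_a, class_b = class_b,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one synthetic subject
#'
#' Deterministic given `(config, label, seed)`: the image is
#' `base_hu + correlated Gaussian field + (class A only)
#' Poisson-scattered Gaussian blobs + i.i.d. noise`, and the ROI is an
#' annulus between an inner "enhancing rim" disc and an outer margin
#' with width at least 10 px (mirroring the minimum peritumoral-zone
#' width of the motivating design).
#'
#' @param config a [cohort_config].
#' @param label `"A"` (HGG-like, positive) or `"B"` (BM-like).
#' @param seed integer seed for this subject.
#' @return An object of class `synthetic_subject`: `image`
#'   ([gray_image]), `roi` ([roi_mask], `source = "synthetic"`), `label`,
#'   `ground_truth` (the generative parameters used).
#' @export
generate_subject <- function(config, label = c("A", "B"), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  label <- match.arg(label)
  pars <- if (label == "A") config$class_a else config$class_b
  nr <- config$image_px[1]; nc <- config$image_px[2]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  px <- matrix(config$base_hu, nr, nc)
  # correlated field: Gaussian-smoothed white noise, rescaled to the
  # requested amplitude (kernel length is the smoothness knob). The
  # "granular" type modulates the field by a pixel-scale alternating
  # sign, concentrating its energy at the resolution limit — the
  # fine-granularity texture of the infiltrated class; the "smooth"
  # type is the long-range vasogenic-edema-like field.
  if (pars$field_amplitude > 0) {
    f <- gaussian_field(nr, nc, pars$field_corr_len_px)
    if (identical(pars$field_type %||% "smooth", "granular")) {
      sgn <- matrix(1, nr, nc)
      sgn[(row(sgn) + col(sgn)) %% 2L == 1L] <- -1
      f <- f * sgn
    }
    px <- px + pars$field_amplitude * f
  }
  if (pars$blob_density > 0) {
    area_cm2 <- nr * nc / 100 # 1 mm spacing convention: 100 px^2 per cm^2
    n_blobs <- stats::rpois(1, pars$blob_density * area_cm2)
    if (n_blobs > 0) {
      br <- stats::runif(n_blobs, 1, nr); bc <- stats::runif(n_blobs, 1, nc)
      rows <- matrix(seq_len(nr), nr, nc); cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (bi in seq_len(n_blobs)) {
        d2 <- (rows - br[bi])^2 + (cols - bc[bi])^2
        px <- px + pars$blob_amplitude_hu * exp(-d2 / (2 * pars$blob_radius_px^2))
      }
    }
  }
  px <- px + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)

  # annulus ROI between enhancing-rim disc and outer margin, width >= 10 px
  roi <- NULL
  # tight annulus geometry: area jitter is kept small (a few %) so that
  # size-dependent statistics (run-length non-uniformity in particular)
  # compare classes rather than ROI areas
  for (attempt in 1:10) {
    ctr <- c(nr, nc) / 2 + stats::runif(2, -0.02, 0.02) * c(nr, nc)
    min_dim <- min(nr, nc)
    inner <- 0.195 * min_dim + stats::runif(1, -1, 1)
    width <- max(10, 0.16 * min_dim + stats::runif(1, -1, 1))
    outer <- inner + width
    if (outer > 0.48 * min_dim) outer <- 0.48 * min_dim
    if (outer - inner < 10) next
    rows <- matrix(seq_len(nr), nr, nc); cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
    m <- d >= inner & d <= outer
    if (sum(m) >= 100L) { roi <- m; break }
  }
  if (is.null(roi)) stop("could not generate an ROI of width >= 10 px", call. = FALSE)

  structure(list(image = gray_image(px, spacing = c(1, 1),
                                    id = sprintf("synth_%s_%d", label, seed)),
                 roi = roi_mask(roi, source = "synthetic"),
                 label = label,
                 ground_truth = c(list(label = label, seed = seed,
                                       base_hu = config$base_hu,
                                       noise_sd = config$noise_sd), pars)),
            class = "synthetic_subject")
}

# unit-variance correlated Gaussian field via separable kernel smoothing
gaussian_field <- function(nr, nc, corr_len) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len <= 0.3) return(w)
  half <- max(1L, ceiling(3 * corr_len))
  k <- stats::dnorm(-half:half, sd = corr_len)
  k <- k / sum(k)
  sm <- apply(w, 2, function(col) conv_reflect(col, k))
  sm <- t(apply(sm, 1, function(row) conv_reflect(row, k)))
  s <- stats::sd(as.vector(sm))
  if (s > 0) sm / s else sm
}

# 1D convolution with reflected boundary
conv_reflect <- function(v, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(v)
  ext <- c(v[pmin(n, half:1)], v, v[pmax(1, n - (1:half) + 1L)])
  as.numeric(stats::filter(ext, k, sides = 2))[(half + 1L):(half + n)]
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> class %s, seed %d, %d ROI px\n",
              x$label, x$ground_truth$seed, sum(x$roi$mask)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' `n_per_class` subjects of each class with per-subject derived seeds
#' (`rng_seed + index`), plus a manifest of ids, labels and generative
#' ground truth.
#'
#' @param config a [cohort_config].
#' @return An object of class `synthetic_cohort`: `subjects` (list of
#'   [generate_subject()] results) and `manifest` (data.frame with
#'   subject_id, label, seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_class
  if (sum(n) == 0L) stop("empty cohort (n_per_class = 0)", call. = FALSE)
  labels <- c(rep("A", n[1]), rep("B", n[2]))
  subjects <- vector("list", sum(n))
  for (i in seq_along(labels)) {
    subjects[[i]] <- generate_subject(config, labels[i],
                                      seed = config$rng_seed + i)
  }
  manifest <- data.frame(
    subject_id = vapply(subjects, function(s) s$image$id, character(1)),
    label = labels,
    seed = config$rng_seed + seq_along(labels))
  structure(list(subjects = subjects, manifest = manifest, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d A / %d B), %dx%d px\n",
              nrow(x$manifest), sum(x$manifest$label == "A"),
              sum(x$manifest$label == "B"),
              x$config$image_px[1], x$config$image_px[2]))
  invisible(x)
}

#' Extract a feature matrix from a cohort
#'
#' Runs [extract_features()] (or a targeted subset of named features,
#' much faster for simulations) on every subject and assembles a
#' [feature_matrix] with class A as the positive class.
#'
#' @param cohort a [generate_cohort()] result.
#' @param profile an [extraction_profile] for full extraction.
#' @param features optional character vector of canonical feature names;
#'   when given, only these are computed (via [single_feature()]
#'   dispatch).
#' @return A [feature_matrix].
#' @export
cohort_features <- function(cohort, profile = extraction_profile(),
                            features = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    if (is.null(features)) {
      extract_features(s$image, s$roi, profile)
    } else {
      q <- normalize_quantize(s$image, s$roi, bits = profile$glcm_bits)
      vapply(features, function(f) {
        sp <- parse_feature_name(f)
        if (sp$family == "GRAD")
          unname(gradient_features(s$image, s$roi, bits = profile$gradient_bits)[f])
        else targeted_feature(q, sp)
      }, numeric(1))
    }
  })
  V <- do.call(rbind, rows)
  rownames(V) <- cohort$manifest$subject_id
  feature_matrix(V, factor(cohort$manifest$label, levels = c("B", "A")),
                 positive = "A")
}

# like single_feature() but reusing an existing quantization
targeted_feature <- function(q, sp) {
  val <- switch(sp$family,
    HIST = {
      p <- if (grepl("^HIST_Perc", sp$name)) as.integer(sub("^HIST_Perc", "", sp$name)) else 10
      histogram_features(q, percentiles = p)[sp$name]
    },
    AR = ar_features(q)[sp$name],
    GLCM = glcm_features(glcm(q, sp$direction, sp$distance),
                         prefix = sprintf("GLCM_%s_d%d_", sp$direction, sp$distance))[sp$name],
    RLM = rlm_features(q, sp$direction)[sp$name],
    WAV = wavelet_energies(q, scales = max(sp$scale, 1L))[sp$name])
  unname(val)
}

#' Synthetic feature matrix with planted effects
#'
#' Direct matrix-level generator (no images): standard normal features,
#' the first `n_effect` of which carry a mean shift of `effect_size`
#' standard deviations in the positive class. Used for calibration
#' studies of the selection and screening stages where image texture is
#' not the object under test.
#'
#' @param n_pos,n_neg subjects per class.
#' @param n_features total feature count.
#' @param n_effect number of features carrying the effect.
#' @param effect_size mean shift in SD units (Cohen's d).
#' @return A [feature_matrix]; effect features are named `effect_1...`,
#'   noise features `noise_1...`.
#' @export
synthetic_feature_matrix <- function(n_pos = 17L, n_neg = 19L,
                                     n_features = 100L, n_effect = 0L,
                                     effect_size = 2) {
  n <- n_pos + n_neg
  V <- matrix(stats::rnorm(n * n_features), n, n_features)
  labels <- rep(c("A", "B"), c(n_pos, n_neg))
  if (n_effect > 0)
    V[labels == "A", seq_len(n_effect)] <-
      V[labels == "A", seq_len(n_effect)] + effect_size
  colnames(V) <- c(if (n_effect > 0) paste0("effect_", seq_len(n_effect)),
                   paste0("noise_", seq_len(n_features - n_effect)))
  feature_matrix(V, factor(labels, levels = c("B", "A")), positive = "A")
}

#' Cohort exclusion cascade bookkeeping
#'
#' Applies an ordered list of exclusion steps to an initial count,
#' logging each step; a negative remainder is an error.
#'
#' @param initial initial record count.
#' @param steps named integer vector (or data.frame with `label` and
#'   `count`) of exclusions, applied in order.
#' @return List with `remaining` and `ledger` (data.frame of label,
#'   excluded, remaining after each step).
#' @export
exclusion_cascade <- function(initial, steps) {
  if (is.data.frame(steps)) {
    labels <- as.character(steps$label); counts <- as.integer(steps$count)
  } else {
    labels <- names(steps) %||% paste0("step_", seq_along(steps))
    counts <- as.integer(steps)
  }
  remaining <- as.integer(initial)
  ledger <- data.frame(label = character(0), excluded = integer(0),
                       remaining = integer(0))
  for (i in seq_along(counts)) {
    remaining <- remaining - counts[i]
    if (remaining < 0)
      stop(sprintf("exclusions exceed available records at step '%s'", labels[i]),
           call. = FALSE)
    ledger <- rbind(ledger, data.frame(label = labels[i], excluded = counts[i],
                                       remaining = remaining))
  }
  list(remaining = remaining, ledger = ledger)
}
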