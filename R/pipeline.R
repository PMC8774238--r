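#' Write a synthetic cohort to disk
#'
#' Stores each subject as a 16-bit PGM image plus a PGM mask and a
#' manifest CSV. PGM holds non-negative integers, so intensities are
#' stored as `round(pixels * slope_inv + offset)` with the affine
#' decoding (`slope = 1/slope_inv`, `intercept = -offset/slope_inv`)
#' recorded in the manifest; [run_pipeline()] applies it on read. The
#' mu+/-3sigma normalization is affine-invariant, so the encoding does
#' not bias texture features beyond the (documented) 1/16 HU rounding.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param slope_inv intensity quantization factor (default 16 steps/HU).
#' @return The manifest data.frame (also written as `manifest.csv`),
#'   with image/mask paths, labels and the decode slope/intercept.
#' @export
cohort_to_disk <- function(cohort, dir, slope_inv = 16) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  offset <- 16384
  rows <- lapply(seq_along(cohort$subjects), function(i) {
    s <- cohort$subjects[[i]]
    img_path <- file.path(dir, sprintf("%s.pgm", s$image$id))
    msk_path <- file.path(dir, sprintf("%s_mask.pgm", s$image$id))
    enc <- round(s$image$pixels * slope_inv + offset)
    write_pgm(gray_image(enc), img_path, maxval = 65535L)
    write_mask(s$roi, msk_path)
    data.frame(subject_id = s$image$id, image_path = img_path,
               mask_path = msk_path, label = s$label,
               slope = 1 / slope_inv, intercept = -offset / slope_inv)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Run the full study pipeline over a cohort manifest
#'
#' Orchestrates extract -> select -> test -> model over a manifest of
#' images and masks, writing every study table to disk. Subjects whose
#' image or mask cannot be read or extracted are excluded and listed in
#' the report; the run aborts if fewer than 3 subjects per class
#' survive. Identical manifest + configuration yield byte-identical
#' outputs.
#'
#' @param manifest data.frame or CSV path with columns `subject_id`,
#'   `image_path`, `mask_path`, `label`, optional `slope`/`intercept`
#'   (affine intensity decode) and optional `age`/`sex` covariates.
#' @param out_dir output directory; `NULL` writes nothing.
#' @param positive label value of the positive class (default `"A"`).
#' @param profile an [extraction_profile].
#' @param k,alpha study parameters passed to [pz_study()].
#' @return List with `study` (the [pz_study()] fit), `features`
#'   (the [feature_matrix]), `excluded` (data.frame of failures) and
#'   `paths` of written artifacts.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, positive = "A",
                         profile = extraction_profile(), k = 10L,
                         alpha = 0.05) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  needed <- c("subject_id", "image_path", "mask_path", "label")
  if (!all(needed %in% names(manifest)))
    stop("manifest must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)

  rows <- list(); excluded <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    res <- tryCatch({
      img <- read_image(r$image_path)
      if (!is.null(r$slope) && is.finite(r$slope))
        img <- gray_image(img$pixels * r$slope +
                            (if (is.null(r$intercept)) 0 else r$intercept),
                          spacing = img$spacing, id = r$subject_id)
      msk <- read_mask(r$mask_path, source = "synthetic")
      extract_features(img, msk, profile)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject_id = r$subject_id, reason = conditionMessage(res))
    } else {
      rows[[r$subject_id]] <- res
    }
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded)
              else data.frame(subject_id = character(0), reason = character(0))
  kept <- manifest[manifest$subject_id %in% names(rows), ]
  if (length(unique(kept$label)) != 2L ||
      any(table(kept$label) < 3L))
    stop("fewer than 3 surviving subjects per class", call. = FALSE)

  V <- do.call(rbind, rows[kept$subject_id])
  rownames(V) <- kept$subject_id
  lab <- factor(kept$label)
  lab <- stats::relevel(lab, ref = setdiff(levels(lab), positive)[1])
  M <- feature_matrix(V, lab, positive = positive)
  covs <- kept[, intersect(c("age", "sex"), names(kept)), drop = FALSE]
  fit <- pz_study(M, covariates = if (ncol(covs)) covs else NULL,
                  k = k, alpha = alpha)

  paths <- NULL
  if (!is.null(out_dir)) paths <- write_study_report(fit, M, out_dir,
                                                     excluded = excluded)
  list(study = fit, features = M, excluded = excluded, paths = paths)
}

#' Write study report artifacts
#'
#' Serializes a fitted study: wide feature CSV, selection JSON, the
#' univariate / per-feature ROC / regression tables as CSV, prediction
#' ROC curve points, and a JSON report embedding a content hash of the
#' configuration for provenance.
#'
#' @param fit a [pz_study()] fit.
#' @param M the [feature_matrix] it was fitted on.
#' @param out_dir output directory (created if needed).
#' @param excluded optional data.frame of excluded subjects.
#' @return Named character vector of written paths, invisibly.
#' @export
write_study_report <- function(fit, M, out_dir, excluded = NULL) {
  stopifnot(inherits(fit, "pz_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(features = file.path(out_dir, "features_wide.csv"),
         selection = file.path(out_dir, "selection.json"),
         univariate = file.path(out_dir, "univariate.csv"),
         roc = file.path(out_dir, "roc.csv"),
         regression = file.path(out_dir, "regression.csv"),
         roc_points = file.path(out_dir, "prediction_roc_points.csv"),
         report = file.path(out_dir, "study.json"))
  utils::write.csv(data.frame(subject_id = rownames(M$values),
                              label = ifelse(M$labels, M$positive, "negative"),
                              M$values, check.names = FALSE),
                   p["features"], row.names = FALSE)
  jsonlite::write_json(list(fisher = fit$selection$fisher$ranked,
                            poe_acc = fit$selection$poe_acc$ranked,
                            unique = fit$selection$unique,
                            overlap = fit$selection$overlap),
                       p["selection"], auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$univariate, p["univariate"], row.names = FALSE)
  rt <- roc_table(fit)
  if (!is.null(rt)) utils::write.csv(rt, p["roc"], row.names = FALSE) else p <- p[names(p) != "roc"]
  if (!is.null(fit$model)) {
    utils::write.csv(fit$model$coefficients, p["regression"], row.names = FALSE)
    utils::write.csv(roc_points(fit$model$fitted, fit$model$labels),
                     p["roc_points"], row.names = FALSE)
  } else {
    p <- p[!names(p) %in% c("regression", "roc_points")]
  }
  report <- list(
    package_version = as.character(utils::packageVersion("peritex")),
    status = fit$status,
    n_pos = fit$n_pos, n_neg = fit$n_neg,
    alpha = fit$alpha, m = fit$m, threshold = fit$threshold,
    n_unique = length(fit$selection$unique),
    n_overlap = length(fit$selection$overlap),
    n_significant = sum(fit$univariate$significant),
    model = if (!is.null(fit$model))
      list(r2 = fit$model$r2, r2_adjusted = fit$model$r2_adjusted,
           mcc = fit$model$mcc),
    prediction = if (!is.null(fit$prediction))
      list(auc = fit$prediction$auc, youden = fit$prediction$youden,
           criterion = fit$prediction$criterion,
           sensitivity = fit$prediction$sensitivity,
           specificity = fit$prediction$specificity),
    excluded = excluded,
    config_hash = config_hash(list(alpha = fit$alpha, m = fit$m,
                                   n = fit$n_pos + fit$n_neg)))
  jsonlite::write_json(report, p["report"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(p)
}

# md5 of the canonical JSON serialization (provenance stamp in reports)
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
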