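#' Pipeline configuration
#'
#' Collects every switch of the image-to-prognosis pipeline with validated
#' values, so a run is fully described by (config, input files).
#'
#' @param manifest path to a manifest CSV with columns `patient_id`,
#'   `roi_id`, `path` (one SHG TIFF per row).
#' @param clinical path to the clinical CSV (columns `patient_id`,
#'   `age_group`, `sex`, `tnm`, `differentiation`, `pni`, `lvi`,
#'   `location`, `os_months`, `event`).
#' @param output_dir directory for stage outputs.
#' @param coefficient_source `"published"` or `"refit"`.
#' @param gmm_components mixture components for segmentation (>= 2).
#' @param min_fiber_length,spur_length,continuation_angle,junction_mode
#'   fiber-network switches, see [extract_fiber_network()].
#' @param orientation_on fea8 input: `"mask"` or `"image"`.
#' @param roc_mode `"event"` (vital status at end of follow-up) or
#'   `"horizon"` (dead by `roc_horizon_months`, censored-before excluded).
#' @param roc_horizon_months horizon for `roc_mode = "horizon"`.
#' @param cv_folds cross-validation folds for the refit path.
#' @param seed integer master seed.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, clinical, output_dir,
                            coefficient_source = c("published", "refit"),
                            gmm_components = 2,
                            min_fiber_length = 10,
                            spur_length = 5,
                            continuation_angle = 45,
                            junction_mode = c("join", "split"),
                            orientation_on = c("mask", "image"),
                            roc_mode = c("event", "horizon"),
                            roc_horizon_months = 36,
                            cv_folds = 5,
                            seed = 1L) {
  coefficient_source <- match.arg(coefficient_source)
  junction_mode <- match.arg(junction_mode)
  orientation_on <- match.arg(orientation_on)
  roc_mode <- match.arg(roc_mode)
  check_that(file.exists(manifest), paste("manifest not found:", manifest))
  check_that(file.exists(clinical), paste("clinical CSV not found:", clinical))
  check_that(gmm_components >= 2, "gmm_components must be >= 2")
  cfg <- list(manifest = manifest, clinical = clinical,
              output_dir = output_dir,
              coefficient_source = coefficient_source,
              gmm_components = as.integer(gmm_components),
              min_fiber_length = min_fiber_length,
              spur_length = spur_length,
              continuation_angle = continuation_angle,
              junction_mode = junction_mode,
              orientation_on = orientation_on,
              roc_mode = roc_mode,
              roc_horizon_months = roc_horizon_months,
              cv_folds = as.integer(cv_folds),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a 12-bit SHG image from a 16-bit grayscale TIFF
#' @param path TIFF file.
#' @return integer matrix of intensities in `[0, 4095]`.
#' @export
read_shg_tiff <- function(path) {
  check_that(file.exists(path), paste("unreadable image:", path))
  x <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

#' Write a 12-bit image as a 16-bit grayscale TIFF
#' @param image integer matrix, values in `[0, 4095]`.
#' @param path destination file.
#' @export
write_shg_tiff <- function(image, path) {
  check_that(all(image >= 0 & image <= 4095), "intensities must be 12-bit")
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Analyze one SHG image: segment, trace, featurize
#'
#' @param image integer intensity matrix.
#' @param cfg a [pipeline_config()]-style list (only the analysis switches
#'   are used); `NULL` for defaults.
#' @param seed seed for the GMM initialization.
#' @return list with `mask`, `network`, `skeleton`, `features`.
#' @export
analyze_image <- function(image, cfg = NULL, seed = 1L) {
  gmm_k <- if (is.null(cfg)) 2 else cfg$gmm_components
  model <- fit_gmm(image, n_components = gmm_k, seed = seed)
  mask <- segment_collagen(image, model)
  skel <- skeletonize_mask(mask)
  net <- extract_fiber_network(
    skel,
    min_fiber_length = if (is.null(cfg)) 10 else cfg$min_fiber_length,
    spur_length = if (is.null(cfg)) 5 else cfg$spur_length,
    continuation_angle = if (is.null(cfg)) 45 else cfg$continuation_angle,
    junction_mode = if (is.null(cfg)) "join" else cfg$junction_mode
  )
  feats <- compute_feature_vector(
    mask, net, image = image,
    orientation_on = if (is.null(cfg)) "mask" else cfg$orientation_on
  )
  list(mask = mask, network = net, skeleton = skel, features = feats,
       gmm = model)
}

#' Run the full image-to-prognosis pipeline
#'
#' Executes segment -> network -> features -> patient aggregation ->
#' Feature-score -> survival evaluation, writing per-stage CSV/JSON
#' artifacts into `cfg$output_dir`. Identical config and seed give
#' identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with `roi_features`, `patient_features`
#'   (including `feature_score` and `risk_group`), `coefficients`, `roc`,
#'   `km`, `cox_univariate`, and the manifest of outputs.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  man <- utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
  check_that(all(c("patient_id", "roi_id", "path") %in% names(man)),
             "manifest needs columns patient_id, roi_id, path")
  clin <- utils::read.csv(cfg$clinical, stringsAsFactors = FALSE)
  missing_pat <- setdiff(unique(man$patient_id), clin$patient_id)
  check_that(length(missing_pat) == 0,
             paste("no clinical record for patient(s):",
                   paste(missing_pat, collapse = ", ")))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  roi_rows <- lapply(seq_len(nrow(man)), function(i) {
    img <- read_shg_tiff(man$path[i])
    res <- analyze_image(img, cfg, seed = cfg$seed)
    c(list(patient_id = man$patient_id[i], roi_id = man$roi_id[i]),
      as.list(res$features))
  })
  roi_features <- do.call(rbind, lapply(roi_rows, as.data.frame))

  pats <- unique(roi_features$patient_id)
  patient_features <- do.call(rbind, lapply(pats, function(p) {
    agg <- aggregate_patient(roi_features[roi_features$patient_id == p,
                                          paste0("fea", 1:8)])
    cbind(data.frame(patient_id = p), as.data.frame(as.list(agg)))
  }))
  pdata <- merge(patient_features, clin, by = "patient_id", sort = TRUE)

  coeffs <- if (cfg$coefficient_source == "published") {
    published_score_coefficients()
  } else {
    fit_ridge_cv(pdata, k_folds = cfg$cv_folds, seed = cfg$seed)
  }
  pdata$feature_score <- compute_feature_score(pdata, coeffs)

  outcome <- if (cfg$roc_mode == "event") {
    pdata$event
  } else {
    h <- cfg$roc_horizon_months
    ifelse(pdata$os_months <= h & pdata$event == 1, 1L,
           ifelse(pdata$os_months > h, 0L, NA_integer_))
  }
  # survival evaluation degrades gracefully on cohorts too small for it
  keep <- !is.na(outcome)
  roc <- tryCatch(roc_youden(pdata$feature_score[keep], outcome[keep]),
                  error = function(e) NULL)
  if (!is.null(roc)) {
    pdata$risk_group <- assign_risk_group(pdata$feature_score, roc$cutoff)
    km <- tryCatch(km_logrank(pdata, pdata$risk_group),
                   error = function(e) NULL)
  } else {
    pdata$risk_group <- NA
    km <- NULL
  }
  cox_uni <- tryCatch(cox_fit(pdata, "feature_score", mode = "univariate"),
                      error = function(e) NULL)

  paths <- list(
    roi_features = file.path(cfg$output_dir, "roi_features.csv"),
    patient_features = file.path(cfg$output_dir, "patient_features.csv"),
    coefficients = file.path(cfg$output_dir, "coefficients.json"),
    roc = file.path(cfg$output_dir, "roc_curve.csv"),
    km = file.path(cfg$output_dir, "km_curves.csv"),
    cox = file.path(cfg$output_dir, "cox_univariate.csv"),
    manifest = file.path(cfg$output_dir, "run_manifest.json")
  )
  utils::write.csv(roi_features, paths$roi_features, row.names = FALSE)
  utils::write.csv(pdata, paths$patient_features, row.names = FALSE)
  jsonlite::write_json(serialize_coefficients(coeffs), paths$coefficients,
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(roc)) utils::write.csv(roc$curve, paths$roc, row.names = FALSE)
  if (!is.null(km)) utils::write.csv(km$curves, paths$km, row.names = FALSE)
  if (!is.null(cox_uni)) {
    utils::write.csv(cox_uni$table, paths$cox, row.names = FALSE)
  }
  jsonlite::write_json(
    list(config = unclass(cfg),
         n_rois = nrow(roi_features),
         n_patients = nrow(pdata),
         auc = if (is.null(roc)) NA else roc$auc,
         cutoff = if (is.null(roc)) NA else roc$cutoff,
         logrank_p = if (is.null(km)) NA else km$logrank_p,
         risk_hr = if (is.null(km)) NA else km$hr),
    paths$manifest, auto_unbox = TRUE, digits = NA, force = TRUE
  )
  invisible(list(roi_features = roi_features, patient_features = pdata,
                 coefficients = coeffs, roc = roc, km = km,
                 cox_univariate = cox_uni, paths = paths))
}

serialize_coefficients <- function(coeffs) {
  list(weights = as.list(coeffs$weights), intercept = coeffs$intercept,
       provenance = coeffs$provenance, penalty = coeffs$penalty,
       standardization = coeffs$standardization)
}

#' Serialize a fiber network to JSON
#'
#' Fibers as coordinate arrays and cross-links as a coordinate array,
#' using 0-based (row, col) pixel coordinates.
#' @param network a `fiber_network`.
#' @param path destination JSON file.
#' @export
write_network_json <- function(network, path) {
  obj <- list(
    fibers = lapply(network$fibers, function(f) {
      list(vertices = unname(f$vertices - 1),
           path_length = f$path_length,
           mean_width = f$mean_width)
    }),
    crosslinks = unname(network$crosslinks - 1),
    image_area = network$image_area
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Split a cohort into training and validation sets
#'
#' Stratified by event status so both sets see a similar event rate. The
#' default proportion mirrors a 107:42 training:validation design.
#'
#' @param cohort data.frame with an `event` column.
#' @param prop training fraction.
#' @param seed integer seed.
#' @return list with `training` and `validation` data.frames.
#' @export
split_cohort <- function(cohort, prop = 107 / 149, seed = 1L) {
  check_that("event" %in% names(cohort), "cohort must contain event")
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$event),
                         function(ix) {
      sample(ix, round(length(ix) * prop))
    }))
    list(training = cohort[sort(idx), , drop = FALSE],
         validation = cohort[-sort(idx), , drop = FALSE])
  })
}

#' Simulate a pipeline-ready study directory
#'
#' Generates per-patient SHG-like images plus the clinical CSV in the
#' layout [run_pipeline()] expects. Patient-level fiber phenotypes are
#' linked to survival: each patient's orientation concentration (and hence
#' the true alignment of their collagen) feeds the proportional-hazards
#' linear predictor through `alignment_beta`, so more aligned collagen
#' shortens survival when `alignment_beta > 0`.
#'
#' @param out_dir study directory to create.
#' @param n_patients number of patients.
#' @param rois_per_patient images per patient.
#' @param image_size tile side, pixels.
#' @param n_fibers fibers per image.
#' @param alignment_beta log-hazard per unit of standardized patient
#'   alignment (true expected fea8 proxy).
#' @param baseline_hazard events per month.
#' @param censoring_rate target censoring fraction.
#' @param seed integer seed.
#' @return invisibly, a list with `manifest`, `clinical` (paths) and the
#'   per-patient ground truth (`kappa`, linear predictor).
#' @export
simulate_study <- function(out_dir, n_patients = 20, rois_per_patient = 2,
                           image_size = 256, n_fibers = 25,
                           alignment_beta = 1, baseline_hazard = 0.05,
                           censoring_rate = 0.2, seed = 1L) {
  check_that(n_patients >= 2, "n_patients must be >= 2")
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE,
             recursive = TRUE)
  with_seed(seed, {
    # patient-level alignment phenotype: log-kappa uniform over a wide range
    kappa <- exp(stats::runif(n_patients, log(0.25), log(32)))
    # standardized alignment proxy drives the hazard
    align <- scale(log(kappa))[, 1]
    lp <- alignment_beta * align
    rate <- baseline_hazard * exp(lp)
    t_event <- stats::rexp(n_patients, rate)
    if (censoring_rate > 0) {
      t_max <- calibrate_censoring(rate, censoring_rate)
      t_cens <- stats::runif(n_patients, 0, t_max)
      event <- as.integer(t_event <= t_cens)
      os <- pmax(pmin(t_event, t_cens), 1e-6)
    } else {
      event <- rep(1L, n_patients)
      os <- t_event
    }

    marg <- clinical_marginals()
    clin <- data.frame(lapply(marg, function(p) {
      sample(names(p), n_patients, replace = TRUE, prob = p)
    }), check.names = FALSE, stringsAsFactors = FALSE)

    ids <- sprintf("P%04d", seq_len(n_patients))
    man <- expand.grid(roi_id = seq_len(rois_per_patient),
                       patient_id = ids, stringsAsFactors = FALSE)
    man <- man[, c("patient_id", "roi_id")]
    man$path <- file.path(out_dir, "images",
                          sprintf("%s_roi%02d.tif", man$patient_id,
                                  man$roi_id))
    img_seeds <- sample.int(.Machine$integer.max, nrow(man))
    for (i in seq_len(nrow(man))) {
      p_ix <- match(man$patient_id[i], ids)
      sp <- fiber_spec(
        n_fibers = n_fibers, size = image_size,
        orientation_mean = stats::runif(1, 0, 180),
        orientation_kappa = kappa[p_ix],
        seed = img_seeds[i]
      )
      g <- generate_fiber_image(sp)
      write_shg_tiff(g$image, man$path[i])
    }

    clinical <- cbind(data.frame(patient_id = ids), clin,
                      data.frame(os_months = os, event = event))
    man_path <- file.path(out_dir, "manifest.csv")
    clin_path <- file.path(out_dir, "clinical.csv")
    utils::write.csv(man, man_path, row.names = FALSE)
    utils::write.csv(clinical, clin_path, row.names = FALSE)
    jsonlite::write_json(
      list(kappa = kappa, linear_predictor = lp, seed = seed),
      file.path(out_dir, "ground_truth.json"), digits = NA
    )
    invisible(list(manifest = man_path, clinical = clin_path,
                   kappa = kappa, linear_predictor = lp))
  })
}
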