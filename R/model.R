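# The covariate-corrected, donor-specific logistic background mutation model.
#
# Training design: every mutated (donor, site) pair is a positive; a uniform
# sample of unmutated (donor, site) pairs provides the negatives, with a
# fixed offset log(1/f0) (f0 = negative-class sampling fraction) in the
# linear predictor so fitted probabilities are calibrated to the full genome.

PROB_CLAMP <- 1e-12
MODEL_SCHEMA <- "nchotspot_model/1"

new_background_model <- function(coefficients, donor_intercepts, normalization,
                                 track_info, use_context, fit_metadata,
                                 flagged_donors = character(0)) {
  structure(list(coefficients = coefficients,
                 donor_intercepts = donor_intercepts,
                 normalization = normalization,
                 track_info = track_info,
                 use_context = use_context,
                 fit_metadata = fit_metadata,
                 flagged_donors = flagged_donors,
                 schema = MODEL_SCHEMA),
            class = "background_model")
}

#' Fit the background mutation model
#'
#' Fits a logistic regression for the per-site, per-donor probability of a
#' somatic SNV: shared covariate coefficients (continuous tracks z-scored,
#' binary tracks as indicators, optionally 31 pyrimidine-collapsed
#' trinucleotide-context indicators) plus one intercept per donor capturing
#' burden heterogeneity. All mutated (donor, site) pairs are positives;
#' `n_background_sites` uniformly sampled unmutated pairs are negatives, and
#' the log inverse of the negative sampling fraction enters as a fixed
#' offset, so predicted probabilities are calibrated to the whole genome.
#' The fit is maximum likelihood (IRLS); a model that does not converge is
#' refused.
#'
#' @param records filtered SNV data frame (see [filter_snvs()]).
#' @param tracks named list of [covariate_track()] covering the genome.
#' @param sequence named character vector of chromosome sequences.
#' @param n_background_sites number of sampled unmutated (donor, site) pairs.
#' @param seed RNG seed for background-site sampling.
#' @param use_context include trinucleotide-context indicators (default TRUE).
#' @param l2 optional ridge penalty (default 0 = plain ML); requires glmnet.
#'   Use when the fit reports complete separation.
#' @param donors optional full donor list; donors present here but absent
#'   from `records` get a floor intercept (probability `1e-12`) and are
#'   flagged.
#' @return an object of class `background_model`.
#' @export
fit_background <- function(records, tracks, sequence,
                           n_background_sites = 200000L, seed = 1L,
                           use_context = TRUE, l2 = 0, donors = NULL) {
  stopifnot(nrow(records) > 0)
  names(sequence) <- harmonize_chrom(names(sequence))
  chrom_len <- nchar(sequence)
  G <- sum(as.numeric(chrom_len))
  donors <- donors %||% sort(unique(records$donor_id))
  zero_donors <- setdiff(donors, unique(records$donor_id))
  fit_donors <- setdiff(donors, zero_donors)

  pos_key <- unique(paste(records$donor_id, records$chrom, records$pos))
  parts <- strsplit(pos_key, " ", fixed = TRUE)
  pos_df <- data.frame(donor = vapply(parts, `[`, character(1), 1),
                       chrom = vapply(parts, `[`, character(1), 2),
                       pos = as.integer(vapply(parts, `[`, character(1), 3)))
  n_pos <- nrow(pos_df)

  neg_df <- withr_seed(seed, {
    d <- sample(fit_donors, n_background_sites, replace = TRUE)
    cn <- sample(names(chrom_len), n_background_sites, replace = TRUE,
                 prob = chrom_len / G)
    p <- floor(runif(n_background_sites) * chrom_len[cn]) + 1L
    data.frame(donor = d, chrom = cn, pos = as.integer(p))
  })
  neg_df <- neg_df[!paste(neg_df$donor, neg_df$chrom, neg_df$pos) %in% pos_key, ]
  n_neg <- nrow(neg_df)
  f0 <- n_neg / (length(fit_donors) * G - n_pos)
  offset <- log(1 / f0)

  all_df <- rbind(pos_df, neg_df)
  y <- c(rep(1, n_pos), rep(0, n_neg))

  normalization <- compute_normalization(all_df$chrom, all_df$pos, tracks)
  X <- build_design(all_df$chrom, all_df$pos, tracks, sequence, normalization,
                    use_context = use_context)
  D <- matrix(0, nrow(all_df), length(fit_donors),
              dimnames = list(NULL, paste0("donor_", fit_donors)))
  D[cbind(seq_len(nrow(all_df)), match(all_df$donor, fit_donors))] <- 1
  M <- cbind(D, X)

  if (l2 > 0) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("l2 > 0 requires the glmnet package")
    }
    pf <- c(rep(0, ncol(D)), rep(1, ncol(X)))   # donor intercepts unpenalized
    gfit <- glmnet::glmnet(M, y, family = "binomial", alpha = 0, lambda = l2,
                           intercept = FALSE, penalty.factor = pf,
                           offset = rep(offset, length(y)), standardize = FALSE)
    beta <- as.numeric(gfit$beta[, 1])
    names(beta) <- rownames(gfit$beta)
    converged <- TRUE
  } else {
    fit <- suppressWarnings(
      glm.fit(M, y, family = binomial(), offset = rep(offset, length(y)))
    )
    beta <- fit$coefficients
    n_aliased <- sum(is.na(beta))
    beta[is.na(beta)] <- 0               # aliased (collinear) columns
    converged <- isTRUE(fit$converged)
    if (!converged) stop("background model fit did not converge")
    if (any(!is.finite(beta)) ||
        max(abs(beta[-seq_len(ncol(D))]), 0) > 30) {
      stop("complete separation detected in the background fit; ",
           "refit with l2 > 0 (ridge regularization)")
    }
  }

  donor_intercepts <- setNames(beta[seq_len(ncol(D))], fit_donors)
  coefs <- beta[-seq_len(ncol(D))]
  if (length(zero_donors)) {
    donor_intercepts[zero_donors] <- qlogis(PROB_CLAMP)
  }
  donor_intercepts <- donor_intercepts[donors]

  track_info <- data.frame(
    name = vapply(tracks, `[[`, character(1), "name"),
    kind = vapply(tracks, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE)

  new_background_model(
    coefficients = coefs,
    donor_intercepts = donor_intercepts,
    normalization = normalization,
    track_info = track_info,
    use_context = use_context,
    fit_metadata = list(n_sites_sampled = n_neg + n_pos, n_positive = n_pos,
                        sampling_fraction = f0, offset = offset,
                        converged = converged, l2 = l2, seed = seed),
    flagged_donors = zero_donors)
}

clamp_prob <- function(p) pmin(pmax(p, PROB_CLAMP), 1 - PROB_CLAMP)

# covariate part of the linear predictor at given sites; tracks without a
# model coefficient are ignored (a true-parameter model may cover a subset)
model_linear_predictor <- function(model, chrom, pos, tracks, sequence) {
  keep <- vapply(tracks, function(t) t$name %in% names(model$coefficients),
                 logical(1))
  absent <- setdiff(model$track_info$name[
    model$track_info$name %in% names(model$coefficients)],
    vapply(tracks, `[[`, character(1), "name"))
  if (length(absent)) stop("model requires missing track(s): ",
                           paste(absent, collapse = ", "))
  X <- build_design(chrom, pos, tracks[keep], sequence, model$normalization,
                    use_context = model$use_context)
  if (is.null(X) || ncol(X) == 0L) return(numeric(length(pos)))
  miss <- setdiff(colnames(X), names(model$coefficients))
  if (length(miss)) stop("model has no coefficient for: ",
                         paste(miss, collapse = ", "))
  drop(X %*% model$coefficients[colnames(X)])
}

donor_intercept <- function(model, donor_id) {
  a <- model$donor_intercepts[donor_id]
  unknown <- is.na(a)
  if (any(unknown)) {
    warning("unknown donor(s) ", paste(unique(donor_id[unknown]), collapse = ", "),
            "; using cohort-mean intercept")
    a[unknown] <- mean(model$donor_intercepts[is.finite(model$donor_intercepts)])
  }
  unname(a)
}

#' Predict per-site, per-donor background mutation probability
#'
#' @param object a fitted [fit_background()] model.
#' @param chrom chromosome name (scalar or vector parallel to `pos`).
#' @param pos 1-based positions.
#' @param donor_id donor identifier (scalar or vector parallel to `pos`);
#'   unknown donors get the cohort-mean intercept with a warning.
#' @param tracks,sequence the covariate tracks and reference sequence.
#' @param type `"response"` (probability, clamped to
#'   \[1e-12, 1 - 1e-12\]) or `"link"` (logit scale).
#' @param ... unused.
#' @return numeric vector of probabilities (or logits).
#' @export
predict.background_model <- function(object, chrom, pos, donor_id, tracks,
                                     sequence, type = c("response", "link"),
                                     ...) {
  type <- match.arg(type)
  g <- model_linear_predictor(object, harmonize_chrom(chrom), pos, tracks,
                              sequence)
  eta <- donor_intercept(object, donor_id) + g
  if (type == "link") eta else clamp_prob(plogis(eta))
}

#' Probability at one site from a feature vector
#'
#' Closed-form evaluation `plogis(alpha_j + beta . x)` from a
#' [site_features()] vector (computed with the model's stored
#' normalization). Errors if a feature has no model coefficient.
#'
#' @param model a `background_model`.
#' @param donor_id donor identifier.
#' @param features a [site_features()] result.
#' @return probability, clamped to \[1e-12, 1 - 1e-12\].
#' @export
predict_site_probability <- function(model, donor_id, features) {
  vals <- features$features
  miss <- setdiff(names(vals), names(model$coefficients))
  if (length(miss)) stop("feature(s) missing from model: ",
                         paste(miss, collapse = ", "))
  eta <- sum(model$coefficients[names(vals)] * vals)
  if (model$use_context) {
    cname <- paste0("ctx_", features$context)
    if (cname %in% names(model$coefficients)) {
      eta <- eta + model$coefficients[[cname]]
    }
  }
  clamp_prob(plogis(donor_intercept(model, donor_id) + eta))
}

#' @export
print.background_model <- function(x, ...) {
  md <- x$fit_metadata
  cat("Background mutation model (logistic, donor-specific intercepts)\n")
  cat(sprintf("  donors: %d (%d flagged zero-mutation)\n",
              length(x$donor_intercepts), length(x$flagged_donors)))
  cat(sprintf("  covariates: %d coefficient(s)%s\n", length(x$coefficients),
              if (x$use_context) " incl. trinucleotide context" else ""))
  cat(sprintf("  training: %d sites (%d positive), sampling fraction %.3g\n",
              md$n_sites_sampled, md$n_positive, md$sampling_fraction))
  cat(sprintf("  converged: %s\n", md$converged))
  invisible(x)
}

#' Model coefficients
#'
#' Continuous covariates are fitted on the z-score scale; `scale = "raw"`
#' divides each continuous coefficient by its stored training standard
#' deviation, returning effects per unit of the original track (comparable
#' with generative truth).
#'
#' @param object a `background_model`.
#' @param scale `"fitted"` (z-score scale, default) or `"raw"`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.background_model <- function(object, scale = c("fitted", "raw"), ...) {
  scale <- match.arg(scale)
  beta <- object$coefficients
  if (scale == "raw") {
    for (nm in names(object$normalization)) {
      if (nm %in% names(beta)) {
        s <- object$normalization[[nm]]["sd"]
        if (s > 0) beta[nm] <- beta[nm] / s
      }
    }
  }
  beta
}

#' Summary of a background model
#'
#' @param object a `background_model`.
#' @param ... unused.
#' @return list with the track-coefficient table and the quartiles of the
#'   donor intercepts, printed compactly.
#' @export
summary.background_model <- function(object, ...) {
  tr <- object$coefficients[object$track_info$name]
  out <- list(track_coefficients = data.frame(feature = names(tr),
                                              estimate = unname(tr)),
              donor_intercept_quartiles =
                quantile(object$donor_intercepts[is.finite(object$donor_intercepts)],
                         c(0, .25, .5, .75, 1)),
              fit_metadata = object$fit_metadata)
  class(out) <- "summary.background_model"
  out
}

#' @export
print.summary.background_model <- function(x, ...) {
  cat("Track coefficients (logit scale):\n")
  print(x$track_coefficients, row.names = FALSE)
  cat("\nDonor intercept quartiles (logit scale):\n")
  print(round(x$donor_intercept_quartiles, 3))
  invisible(x)
}

#' Simulate mutation sets from a fitted background model
#'
#' Draws `nsim` cohorts site-by-site under the fitted probabilities — the
#' parametric-bootstrap counterpart of [simulate_mutations()].
#'
#' @param object a `background_model`.
#' @param nsim number of replicate cohorts.
#' @param seed RNG seed.
#' @param tracks,sequence covariate tracks and reference sequence.
#' @param ... unused.
#' @return list of mutation data frames.
#' @export
simulate.background_model <- function(object, nsim = 1, seed = NULL, tracks,
                                      sequence, ...) {
  names(sequence) <- harmonize_chrom(names(sequence))
  withr_seed(seed %||% 1L, {
    lapply(seq_len(nsim), function(k) {
      per_chrom <- lapply(names(sequence), function(cn) {
        L <- nchar(sequence[[cn]])
        g <- model_linear_predictor(object, cn, seq_len(L), tracks, sequence)
        seq_chars <- strsplit(sequence[[cn]], "", fixed = TRUE)[[1]]
        do.call(rbind, lapply(names(object$donor_intercepts), function(d) {
          p <- clamp_prob(plogis(object$donor_intercepts[[d]] + g))
          hit <- which(runif(L) < p)
          if (!length(hit)) return(NULL)
          ref <- seq_chars[hit]
          data.frame(donor_id = d, cancer_type = NA_character_, chrom = cn,
                     pos = hit, ref = ref, alt = draw_alt(ref),
                     stringsAsFactors = FALSE)
        }))
      })
      out <- do.call(rbind, per_chrom)
      if (is.null(out)) empty_records()[mutation_columns] else {
        out <- out[order(out$donor_id, out$pos), ]
        rownames(out) <- NULL
        out
      }
    })
  })
}

#' Save / load a background model
#'
#' Lossless JSON round-trip with a schema-version tag; [load_model()] refuses
#' files with a different schema.
#'
#' @param model a `background_model`.
#' @param path file path.
#' @return `save_model` the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "background_model"))
  obj <- list(schema = MODEL_SCHEMA,
              coefficients = as.list(model$coefficients),
              donor_intercepts = as.list(model$donor_intercepts),
              normalization = lapply(model$normalization, as.list),
              track_info = model$track_info,
              use_context = model$use_context,
              fit_metadata = model$fit_metadata,
              flagged_donors = model$flagged_donors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, MODEL_SCHEMA)) {
    stop("model schema mismatch: expected ", MODEL_SCHEMA, ", found ",
         obj$schema %||% "<none>")
  }
  norm <- lapply(obj$normalization, function(x)
    c(mean = as.numeric(x$mean), sd = as.numeric(x$sd)))
  new_background_model(
    coefficients = unlist(obj$coefficients),
    donor_intercepts = unlist(obj$donor_intercepts),
    normalization = norm,
    track_info = as.data.frame(obj$track_info),
    use_context = isTRUE(obj$use_context),
    fit_metadata = obj$fit_metadata,
    flagged_donors = as.character(obj$flagged_donors %||% character(0)))
}

#' Background model holding known (true) parameters
#'
#' Builds a `background_model` directly from a [cohort_spec()]'s generative
#' parameters (raw-scale coefficients, per-donor intercepts, no context
#' term). Useful for null-calibration studies where the true model is
#' supplied to the scan.
#'
#' @param spec a [cohort_spec()].
#' @return a `background_model`.
#' @export
true_background_model <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  new_background_model(
    coefficients = spec$true_coefficients,
    donor_intercepts = setNames(spec$donor_log_offsets, donor_ids_of(spec)),
    normalization = list(),              # raw-scale coefficients
    track_info = data.frame(name = spec$covariate_specs$name,
                            kind = spec$covariate_specs$kind,
                            stringsAsFactors = FALSE),
    use_context = FALSE,
    fit_metadata = list(n_sites_sampled = 0L, n_positive = 0L,
                        sampling_fraction = NA_real_, offset = 0,
                        converged = TRUE, l2 = 0, seed = spec$seed))
}
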