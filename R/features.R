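#' Subjects-by-channels feature table
#'
#' One scalar feature per subject and channel, plus group labels. The
#' standard container handed to the decoding stage.
#'
#' @param values Numeric matrix, subjects x channels.
#' @param feature_name Name of the feature (e.g. `"sd_alpha_cf"`).
#' @param condition_tag `"pre"`, `"post"` or `"delta"`.
#' @param labels Character/factor vector of `"high"`/`"low"`, one per row.
#' @param subject_ids Character vector, one per row.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, feature_name, condition_tag, labels,
                          subject_ids = rownames(values)) {
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  if (any(!is.finite(values)))
    stop("feature table contains missing cells; apply exclusion handling first")
  labels <- as.character(labels)
  if (!all(labels %in% c("high", "low")))
    stop("labels must be 'high' or 'low'")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%02d", seq_len(nrow(values)))
  rownames(values) <- subject_ids
  structure(list(values = values, feature_name = feature_name,
                 condition_tag = condition_tag, labels = labels,
                 subject_ids = subject_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s [%s]: %d subjects (%d high / %d low) x %d channels\n",
              x$feature_name, x$condition_tag, nrow(x$values),
              sum(x$labels == "high"), sum(x$labels == "low"),
              ncol(x$values)))
  invisible(x)
}

#' Per-channel variability of one spectral parameter
#'
#' The sample standard deviation (n - 1 denominator) of the chosen
#' parameter across the time series of each channel, over windows where
#' the parameter is available (complete case). Channels with fewer than
#' two non-missing windows yield `NA`.
#'
#' @param pts A [parameterize_recording()] result.
#' @param parameter One of `"alpha_cf"`, `"alpha_amplitude"`,
#'   `"alpha_width"`, `"offset"`, `"exponent"`, `"mse"`.
#' @return Named numeric vector, one value per channel.
#' @examples
#' # constant series have zero variability; {9, 11} gives sqrt(2)
#' sd(c(9, 11)) == sqrt(2)
#' @export
compute_variability <- function(pts, parameter) {
  stopifnot(inherits(pts, "parameter_ts"))
  parameter <- match.arg(parameter, c("alpha_cf", "alpha_amplitude",
                                      "alpha_width", "offset", "exponent",
                                      "mse"))
  vapply(pts$channels, function(d) {
    v <- d[[parameter]]
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else sd(v)
  }, numeric(1))
}

#' Post-minus-pre contrast of two feature tables
#'
#' Elementwise `post - pre` for matching subjects and channels; the result
#' carries `condition_tag = "delta"`.
#'
#' @param post,pre [feature_table()] objects for the same subjects,
#'   channels and feature.
#' @return A `feature_table` tagged `"delta"`.
#' @export
compute_delta <- function(post, pre) {
  stopifnot(inherits(post, "feature_table"), inherits(pre, "feature_table"))
  if (!identical(post$subject_ids, pre$subject_ids))
    stop("subject sets differ between post and pre tables")
  if (!identical(dim(post$values), dim(pre$values)))
    stop("channel sets differ between post and pre tables")
  if (!identical(post$labels, pre$labels))
    stop("group labels differ between post and pre tables")
  feature_table(post$values - pre$values, post$feature_name, "delta",
                post$labels, post$subject_ids)
}

#' Assemble the decoding feature tables for a cohort
#'
#' Reduces per-subject parameter time series to the pre-induction and
#' delta-induction (post minus pre) variability tables for the five
#' spectral parameters, plus the goodness-of-fit control features
#' (`mean_mse`, `sd_mse`). Subjects with a flagged channel (alpha coverage
#' below the floor) in either condition are excluded from every table,
#' mirroring the handling of subjects whose alpha peaks could not be
#' modelled.
#'
#' @param cohort_pts Named list, one entry per subject:
#'   `list(pre = parameter_ts, post = parameter_ts, group = "high"|"low")`.
#' @param lz Optional named list per subject:
#'   `list(pre = lz_result, post = lz_result)`; adds `mean_lz` tables.
#' @param verbose Report exclusions?
#' @return Named list of [feature_table()]s, keys like
#'   `"sd_alpha_cf.pre"`, `"sd_alpha_cf.delta"`, ...; attribute
#'   `"excluded"` lists dropped subjects. Main family:
#'   sd_alpha_cf, sd_alpha_amplitude, sd_alpha_width, sd_offset,
#'   sd_exponent.
#' @export
assemble_feature_tables <- function(cohort_pts, lz = NULL, verbose = FALSE) {
  ids <- names(cohort_pts)
  if (is.null(ids)) stop("`cohort_pts` must be a named list of subjects")
  for (id in ids) {
    if (is.null(cohort_pts[[id]]$pre) || is.null(cohort_pts[[id]]$post))
      stop(sprintf("subject %s is missing a condition", id))
  }
  excluded <- ids[vapply(ids, function(id) {
    any(cohort_pts[[id]]$pre$flagged) || any(cohort_pts[[id]]$post$flagged)
  }, logical(1))]
  keep <- setdiff(ids, excluded)
  if (length(keep) < 4)
    stop("fewer than 4 subjects remain after the alpha-coverage exclusion")
  if (verbose && length(excluded) > 0)
    message(sprintf("excluding %d subject(s) with low alpha coverage: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  labels <- vapply(keep, function(id) cohort_pts[[id]]$group, character(1))

  sd_feats <- c(sd_alpha_cf = "alpha_cf", sd_alpha_amplitude = "alpha_amplitude",
                sd_alpha_width = "alpha_width", sd_offset = "offset",
                sd_exponent = "exponent", sd_mse = "mse")
  stack_rows <- function(f) {
    m <- do.call(rbind, lapply(keep, f))
    rownames(m) <- keep
    m
  }
  per_cond <- function(cond) {
    mats <- lapply(sd_feats, function(p) {
      stack_rows(function(id) compute_variability(cohort_pts[[id]][[cond]], p))
    })
    mats$mean_mse <- stack_rows(function(id) {
      vapply(cohort_pts[[id]][[cond]]$channels,
             function(d) mean(d$mse, na.rm = TRUE), numeric(1))
    })
    if (!is.null(lz)) {
      mats$mean_lz <- stack_rows(function(id) lz[[id]][[cond]]$mean_normalized)
    }
    mats
  }
  pre <- per_cond("pre")
  post <- per_cond("post")

  out <- list()
  for (nm in names(pre)) {
    tp <- feature_table(pre[[nm]], nm, "pre", labels, keep)
    tq <- feature_table(post[[nm]], nm, "post", labels, keep)
    out[[paste0(nm, ".pre")]] <- tp
    out[[paste0(nm, ".delta")]] <- compute_delta(tq, tp)
  }
  structure(out, excluded = excluded,
            main_features = paste0("sd_", c("alpha_cf", "alpha_amplitude",
                                            "alpha_width", "offset",
                                            "exponent")))
}
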