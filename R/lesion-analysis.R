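#' Lesion-level matching of a prediction against ground-truth lesions
#'
#' Connected components of the prediction are matched to ground-truth lesions
#' by voxel overlap (at least `min_overlap` shared voxels, default 1 — the
#' literal criterion):
#' \itemize{
#'   \item a GT lesion overlapped by no predicted component is *missed*;
#'   \item a predicted component overlapping no GT lesion is a *spurious
#'     focus*;
#'   \item *fragmentation* of a GT lesion is the number of predicted
#'     components overlapping it (2+ means the method split the lesion).
#' }
#' A single predicted component overlapping two GT lesions detects both and
#' is not spurious.
#'
#' @param pred predicted mask ([binary_volume()]).
#' @param gt_lesions ground-truth lesions (a `lesion_map`, e.g. from
#'   [confirm_lesions()] or [connected_components()]).
#' @param connectivity connectivity for predicted components (default 26).
#' @param min_overlap minimum shared voxels to count as overlap (default 1).
#' @return object of class `lesion_match_report`: list with `n_gt_lesions`,
#'   `n_pred_lesions`, `n_missed`, `n_detected`, `n_spurious`,
#'   `fragmentation` (integer per GT lesion), `detected` (logical per GT
#'   lesion), `spurious` (logical per predicted component).
#' @export
match_lesions <- function(pred, gt_lesions, connectivity = 26,
                          min_overlap = 1) {
  stopifnot(is_binary_volume(pred), inherits(gt_lesions, "lesion_map"))
  if (!identical(dim(pred$data), dim(gt_lesions$labels)))
    stop("grid mismatch between prediction and ground-truth lesions")
  pc <- connected_components(pred, connectivity)
  ng <- gt_lesions$n
  np <- pc$n
  overlap <- matrix(0L, nrow = ng, ncol = np)
  if (ng > 0 && np > 0) {
    both <- gt_lesions$labels > 0L & pc$labels > 0L
    if (any(both)) {
      tab <- table(gt = gt_lesions$labels[both], pred = pc$labels[both])
      overlap[cbind(as.integer(rownames(tab))[row(tab)],
                    as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
    }
  }
  hit <- overlap >= min_overlap
  fragmentation <- if (ng > 0) as.integer(rowSums(hit)) else integer(0)
  detected <- fragmentation > 0L
  spurious <- if (np > 0) !apply(hit, 2, any) else logical(0)
  if (np == 0) spurious <- logical(0)
  structure(list(
    n_gt_lesions = ng, n_pred_lesions = np,
    n_detected = sum(detected), n_missed = ng - sum(detected),
    n_spurious = sum(spurious),
    fragmentation = fragmentation, detected = detected, spurious = spurious
  ), class = "lesion_match_report")
}

#' @export
print.lesion_match_report <- function(x, ...) {
  cat(sprintf(
    "<lesion_match_report> GT %d (missed %d), predicted %d (spurious %d)\n",
    x$n_gt_lesions, x$n_missed, x$n_pred_lesions, x$n_spurious))
  invisible(x)
}

#' Cohort-level lesion-count distribution tables
#'
#' Aggregates per-patient lesion match reports into the per-method
#' distribution tables of a cohort analysis: how many patients got each
#' predicted-lesion count, each missed-lesion count (with percentages over the
#' lesion-bearing subcohort) and each spurious-focus count (percentages over
#' the full cohort).
#'
#' @param reports named (by method) list of lists of `lesion_match_report`,
#'   or a single method's list of reports.
#' @return list of three `data.frame`s: `predicted` (method, count,
#'   n_patients), `missed` (method, count, n_patients, pct over patients with
#'   at least one GT lesion), `spurious` (method, count, n_patients, pct over
#'   all patients).
#' @export
cohort_tables <- function(reports) {
  if (length(reports) && inherits(reports[[1]], "lesion_match_report"))
    reports <- list(method = reports)
  stopifnot(length(reports) >= 1)
  hist_df <- function(counts, method) {
    tab <- table(counts)
    data.frame(method = method, count = as.integer(names(tab)),
               n_patients = as.integer(tab), stringsAsFactors = FALSE)
  }
  pred <- missed <- spur <- list()
  for (m in names(reports)) {
    rs <- reports[[m]]
    n_all <- length(rs)
    n_gt <- vapply(rs, function(r) as.numeric(r$n_gt_lesions), numeric(1))
    n_lesional <- sum(n_gt > 0)
    p <- hist_df(vapply(rs, function(r) as.numeric(r$n_pred_lesions),
                        numeric(1)), m)
    mi <- hist_df(vapply(rs[n_gt > 0], function(r) as.numeric(r$n_missed),
                         numeric(1)), m)
    if (nrow(mi)) mi$pct <- 100 * mi$n_patients / n_lesional
    s <- hist_df(vapply(rs, function(r) as.numeric(r$n_spurious),
                        numeric(1)), m)
    s$pct <- 100 * s$n_patients / n_all
    pred[[m]] <- p; missed[[m]] <- mi; spur[[m]] <- s
  }
  list(predicted = do.call(rbind, c(pred, make.row.names = FALSE)),
       missed = do.call(rbind, c(missed, make.row.names = FALSE)),
       spurious = do.call(rbind, c(spur, make.row.names = FALSE)))
}

#' False-positive-patient percentage
#'
#' Percentage of lesion-free patients (empty ground truth) for whom a method
#' predicted any cancerous voxel. The denominator is restricted to the
#' lesion-free subcohort. Computed overall and, when a `fold` column is
#' present, per fold.
#'
#' @param records `data.frame` of [evaluate_patient()] rows (any number of
#'   methods), optionally with a `fold` column.
#' @return `data.frame` with columns `method_id`, `fold` (`"all"` for the
#'   overall row), `n_lesion_free`, `n_false_positive`, `pct`.
#' @export
false_positive_patient_rate <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("method_id", "has_gt_lesion",
                  "false_positive_patient") %in% names(records)))
  neg <- records[!records$has_gt_lesion, , drop = FALSE]
  if (nrow(neg) == 0) {
    warning("no lesion-free patients: false-positive-patient rate undefined")
    return(data.frame(method_id = character(0), fold = character(0),
                      n_lesion_free = integer(0), n_false_positive = integer(0),
                      pct = numeric(0), stringsAsFactors = FALSE))
  }
  one <- function(df, fold) {
    agg <- lapply(split(df, df$method_id), function(d)
      data.frame(method_id = d$method_id[1], fold = fold,
                 n_lesion_free = nrow(d),
                 n_false_positive = sum(d$false_positive_patient),
                 pct = 100 * sum(d$false_positive_patient) / nrow(d),
                 stringsAsFactors = FALSE))
    do.call(rbind, c(agg, make.row.names = FALSE))
  }
  out <- one(neg, "all")
  if ("fold" %in% names(neg))
    for (f in sort(unique(neg$fold)))
      out <- rbind(out, one(neg[neg$fold == f, , drop = FALSE],
                            as.character(f)))
  out
}
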