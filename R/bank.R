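#' Build a validated donor-bank index
#'
#' The virtual bone bank table: one row per banked donor bone with its ABC
#' measurements and (optionally) paths to its mesh and landmark files.
#' Required columns: `donor_id`, `side`, `bone`, `a_mm`, `b_mm`, `c_mm`;
#' optional: `mesh_path`, `landmarks_path`. Duplicate donor ids and
#' negative measures are rejected.
#'
#' @param records data frame of bank records (e.g. read from a bank CSV).
#' @param root optional directory against which relative mesh/landmark
#'   paths are resolved.
#' @return a `bank_index`: the validated data frame.
#' @export
build_index <- function(records, root = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) < 1L) stop("bank needs at least one record", call. = FALSE)
  required <- c("donor_id", "side", "bone", "a_mm", "b_mm", "c_mm")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("bank records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dup <- records$donor_id[duplicated(records$donor_id)]
  if (length(dup))
    stop("duplicate donor_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  meas <- as.matrix(records[, c("a_mm", "b_mm", "c_mm")])
  if (anyNA(meas) || any(meas < 0))
    stop("ABC measures must be non-negative numbers", call. = FALSE)
  bad_side <- !records$side %in% c("left", "right")
  if (any(bad_side))
    stop("side must be 'left' or 'right' (bad: ",
         paste(unique(records$donor_id[bad_side]), collapse = ", "), ")",
         call. = FALSE)
  structure(records, root = root, class = c("bank_index", "data.frame"))
}

#' Read a bank CSV into an index
#'
#' @param path bank CSV path (schema of [generate_bank()]).
#' @return a `bank_index`; relative mesh/landmark paths resolve against the
#'   CSV's directory.
#' @export
read_bank <- function(path) {
  if (!file.exists(path)) stop("bank CSV not found: ", path, call. = FALSE)
  build_index(read.csv(path, stringsAsFactors = FALSE),
              root = dirname(path))
}

bank_file <- function(index, relpath) {
  root <- attr(index, "root")
  if (is.null(root) || is.na(relpath) || relpath == "" ||
      file.exists(relpath)) return(relpath)
  file.path(root, relpath)
}

#' Screen the bank for donors closest in ABC size
#'
#' The screening step of allograft selection: donors are ranked by their
#' distance to the host's ABC measurements, and the best `k` are forwarded
#' to surface matching. The default metric is the weighted Euclidean
#' distance `sqrt(wa dA^2 + wb dB^2 + wc dC^2)` with unit weights;
#' `metric = "maxabs"` uses the largest weighted absolute per-measure
#' difference instead. Ties are broken by `donor_id` (lexicographic), so
#' the ordering is fully deterministic.
#'
#' @param index a `bank_index` from [build_index()] or [read_bank()].
#' @param host_abc an [abc_measurement()] of the host's mirror model.
#' @param k number of candidates to return (default 5).
#' @param weights positive length-3 weights for (A, B, C).
#' @param side optional filter: keep only donors of this side. Screening
#'   normally matches donors of the same chirality as the resected side.
#' @param bone optional filter on the bone type.
#' @param metric `"euclidean"` (default) or `"maxabs"`.
#' @return a `screening_result` data frame: `donor_id`, `abc_distance_mm`,
#'   per-measure deltas (`delta_a_mm` etc., donor minus host), and the
#'   donor columns, sorted ascending by distance. Empty after filtering
#'   triggers a warning and a zero-row result.
#' @export
screen_bank <- function(index, host_abc, k = 5, weights = c(1, 1, 1),
                        side = NULL, bone = NULL,
                        metric = c("euclidean", "maxabs")) {
  if (!inherits(index, "bank_index"))
    stop("expected a bank_index", call. = FALSE)
  metric <- match.arg(metric)
  host_abc <- as.numeric(host_abc)
  if (length(host_abc) != 3L || anyNA(host_abc))
    stop("host_abc must be three numbers (A, B, C)", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  weights <- as.numeric(weights)
  if (length(weights) != 3L || any(weights <= 0))
    stop("weights must be three positive numbers", call. = FALSE)
  keep <- rep(TRUE, nrow(index))
  if (!is.null(side)) keep <- keep & index$side == side
  if (!is.null(bone)) keep <- keep & index$bone == bone
  sub <- as.data.frame(index)[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("no donors pass the screening filters")
    res <- data.frame(donor_id = character(), abc_distance_mm = numeric(),
                      delta_a_mm = numeric(), delta_b_mm = numeric(),
                      delta_c_mm = numeric())
    return(structure(res, class = c("screening_result", "data.frame")))
  }
  deltas <- sweep(as.matrix(sub[, c("a_mm", "b_mm", "c_mm")]), 2, host_abc)
  dist <- switch(metric,
                 euclidean = sqrt((deltas^2) %*% weights)[, 1],
                 maxabs = apply(abs(deltas) * rep(sqrt(weights),
                                                  each = nrow(deltas)),
                                1, max))
  ord <- order(dist, sub$donor_id)
  take <- head(ord, k)
  res <- cbind(data.frame(donor_id = sub$donor_id[take],
                          abc_distance_mm = dist[take],
                          delta_a_mm = deltas[take, 1],
                          delta_b_mm = deltas[take, 2],
                          delta_c_mm = deltas[take, 3],
                          stringsAsFactors = FALSE),
               sub[take, setdiff(names(sub), "donor_id"), drop = FALSE])
  rownames(res) <- NULL
  structure(res, root = attr(index, "root"),
            class = c("screening_result", "data.frame"))
}
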