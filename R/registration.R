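#' Registration configuration
#'
#' Parameters of the trimmed iterative-closest-point refinement. Trimming
#' discards the worst correspondences each iteration, which keeps partial,
#' tumor-eroded host models from dragging the fit; 10% is the default and
#' hosts with large defects benefit from more. Scaling is never estimated:
#' allograft selection compares true sizes, so only rotation and
#' translation are fit.
#'
#' @param max_iterations maximum ICP iterations (default 100).
#' @param convergence_tol_mm stop when the trimmed mean distance changes by
#'   less than this between iterations (default 1e-4 mm).
#' @param trim_fraction fraction of worst correspondences discarded per
#'   iteration, in `[0, 0.5)` (default 0.1).
#' @param sample_size number of source points used (default 5000); larger
#'   sources are subsampled deterministically.
#' @param seed integer seed controlling subsampling only.
#' @param init_mode how [register_surfaces()] initializes: `"landmarks"`,
#'   `"principal_axes"`, or `"identity"`.
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(max_iterations = 100, convergence_tol_mm = 1e-4,
                                trim_fraction = 0.1, sample_size = 5000,
                                seed = 1L,
                                init_mode = c("landmarks", "principal_axes",
                                              "identity")) {
  init_mode <- match.arg(init_mode)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (convergence_tol_mm <= 0) stop("convergence_tol_mm must be > 0",
                                    call. = FALSE)
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)", call. = FALSE)
  if (sample_size < 3) stop("sample_size must be >= 3", call. = FALSE)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol_mm = convergence_tol_mm,
                 trim_fraction = trim_fraction,
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed), init_mode = init_mode),
            class = "registration_config")
}

# closed-form least-squares rigid fit (Kabsch/Procrustes, no scaling):
# minimizes sum ||R s_i + t - t_i||^2; reflection excluded via sign fix.
kabsch <- function(src, dst) {
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' Rigid landmark alignment (closed form)
#'
#' Least-squares rigid transform (rotation + translation, no scaling, no
#' reflection) mapping the source landmarks onto the target landmarks,
#' paired by name. This is the registration initializer when both host
#' mirror and donor carry the six ABC landmarks; both sets must already
#' have the same chirality (the host side is mirrored first).
#'
#' @param source,target [landmark_set()] objects (or 3-column matrices with
#'   matching row order).
#' @return a [rigid_transform()] minimizing the sum of squared pair
#'   distances.
#' @export
landmark_align <- function(source, target) {
  src <- if (inherits(source, "landmark_set")) {
    validate_landmarks(source)
    landmarks_matrix(source)
  } else as.matrix(source)
  dst <- if (inherits(target, "landmark_set")) {
    validate_landmarks(target)
    landmarks_matrix(target)
  } else as.matrix(target)
  if (nrow(src) != nrow(dst) || nrow(src) < 3L)
    stop("need >= 3 paired landmarks", call. = FALSE)
  sv <- svd(sweep(src, 2, colMeans(src)))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate landmark configuration (collinear or coincident)",
         call. = FALSE)
  kabsch(src, dst)
}

#' Trimmed iterative-closest-point rigid registration
#'
#' Iterates: (a) find the closest point on the target surface for every
#' transformed source point (exact point-to-triangle via a BVH), (b)
#' discard the worst `trim_fraction` by distance, (c) refit the rigid
#' transform in closed form on the retained pairs. Stops when the trimmed
#' mean distance changes by less than `convergence_tol_mm`, or at
#' `max_iterations`. The trimmed mean is non-increasing across iterations.
#'
#' @param source a [point_cloud()] (>= 3 points) on the host mirror.
#' @param target a [surface_mesh()] (the donor).
#' @param init initial [rigid_transform()] (e.g. from [landmark_align()] or
#'   [principal_axes_init()]).
#' @param config a [registration_config()].
#' @return a `registration_result`: list with `transform`
#'   ([rigid_transform()]), `iterations_used`, `final_mean_distance_mm`,
#'   `converged`, and `mean_distance_trace` (one trimmed mean per
#'   iteration).
#' @export
icp_register <- function(source, target, init = rigid_transform(),
                         config = registration_config()) {
  if (!inherits(source, "point_cloud"))
    stop("source must be a point_cloud", call. = FALSE)
  validate_mesh(target)
  if (nrow(target$faces) < 1L) stop("target mesh is empty", call. = FALSE)
  pts <- source$points
  if (nrow(pts) < 3L) stop("source needs >= 3 points", call. = FALSE)
  if (nrow(pts) > config$sample_size) {
    sel <- with_seed(config$seed,
                     sample.int(nrow(pts), config$sample_size))
    pts <- pts[sel, , drop = FALSE]
  }
  n <- nrow(pts)
  keep_n <- n - floor(config$trim_fraction * n)
  if (keep_n < 3L)
    stop("trimming leaves fewer than 3 correspondences", call. = FALSE)
  bvh <- cpp_bvh_build(target$vertices, target$faces - 1L)
  transform <- init
  prev_mean <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(config$max_iterations)) {
    iters <- it
    moved <- apply_transform(pts, transform)
    q <- cpp_bvh_query(bvh, moved)
    ord <- order(q$distance)[seq_len(keep_n)]
    mean_d <- mean(q$distance[ord])
    trace <- c(trace, mean_d)
    transform <- kabsch(pts[ord, , drop = FALSE],
                        q$point[ord, , drop = FALSE])
    if (abs(prev_mean - mean_d) < config$convergence_tol_mm) {
      converged <- TRUE
      break
    }
    prev_mean <- mean_d
  }
  moved <- apply_transform(pts, transform)
  q <- cpp_bvh_query(bvh, moved)
  final_mean <- mean(sort(q$distance)[seq_len(keep_n)])
  structure(list(transform = transform, iterations_used = iters,
                 final_mean_distance_mm = final_mean, converged = converged,
                 mean_distance_trace = trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s after %d iteration(s), trimmed mean %.4g mm\n",
              if (x$converged) "converged" else "stopped",
              x$iterations_used, x$final_mean_distance_mm))
  invisible(x)
}

#' Landmark-free initialization by centroids and principal axes
#'
#' For diaphyseal and transepiphyseal segments, where natural landmarks are
#' unavailable, registration is initialized by aligning centroids and the
#' principal axes of the two point sets. The four proper-rotation axis-sign
#' combinations are enumerated and the candidate with the smallest mean
#' source-to-target distance wins. Near-degenerate inertia (adjacent
#' principal-moment ratio below 1.01, e.g. a sphere) triggers an ambiguity
#' warning and an identity-rotation, centroid-only fallback.
#'
#' @param source a [point_cloud()].
#' @param target a [surface_mesh()] or [point_cloud()].
#' @param n_eval number of source points used to evaluate candidates.
#' @param seed seed for the evaluation subsample.
#' @return a [rigid_transform()].
#' @export
principal_axes_init <- function(source, target, n_eval = 1000, seed = 1L) {
  if (!inherits(source, "point_cloud"))
    stop("source must be a point_cloud", call. = FALSE)
  spts <- source$points
  tpts <- if (inherits(target, "surface_mesh")) target$vertices
          else if (inherits(target, "point_cloud")) target$points
          else stop("target must be a surface_mesh or point_cloud",
                    call. = FALSE)
  cs <- colMeans(spts)
  ct <- colMeans(tpts)
  es <- eigen(stats::cov(spts), symmetric = TRUE)
  et <- eigen(stats::cov(tpts), symmetric = TRUE)
  ratios <- es$values[1:2] / es$values[2:3]
  if (any(!is.finite(ratios)) || any(ratios < 1.01)) {
    warning("principal moments nearly degenerate: axis alignment is ",
            "ambiguous; falling back to centroid translation only")
    return(rigid_transform(diag(3), ct - cs))
  }
  Vs <- es$vectors
  Vt <- et$vectors
  if (det(Vs) < 0) Vs[, 3] <- -Vs[, 3]
  if (det(Vt) < 0) Vt[, 3] <- -Vt[, 3]
  sel <- if (nrow(spts) > n_eval)
    with_seed(seed, sample.int(nrow(spts), n_eval)) else seq_len(nrow(spts))
  eval_pts <- spts[sel, , drop = FALSE]
  use_bvh <- inherits(target, "surface_mesh") && nrow(target$faces) > 0
  bvh <- if (use_bvh) cpp_bvh_build(target$vertices, target$faces - 1L)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL
  best_d <- Inf
  for (s in signs) {
    R <- Vt %*% diag(s) %*% t(Vs)
    tr <- rigid_transform(R, ct - as.numeric(R %*% cs))
    moved <- apply_transform(eval_pts, tr)
    d <- if (use_bvh) mean(cpp_bvh_query(bvh, moved)$distance)
         else mean(sqrt(rowSums((moved - tpts[nearest_rows(tpts, moved), ,
                                              drop = FALSE])^2)))
    if (d < best_d) {
      best_d <- d
      best <- tr
    }
  }
  best
}

# brute-force nearest row lookup (small point-cloud targets only)
nearest_rows <- function(ref, qry) {
  vapply(seq_len(nrow(qry)), function(i) {
    which.min(colSums((t(ref) - qry[i, ])^2))
  }, integer(1))
}

#' Register a host mirror onto a donor (initialize + refine)
#'
#' Convenience wrapper combining initialization and trimmed ICP: landmark
#' alignment when both landmark sets are given (`init_mode = "landmarks"`),
#' principal-axes alignment otherwise.
#'
#' @param source_mesh host-mirror [surface_mesh()].
#' @param target_mesh donor [surface_mesh()].
#' @param source_landmarks,target_landmarks optional [landmark_set()]s.
#' @param config a [registration_config()].
#' @return a `registration_result` (see [icp_register()]).
#' @export
register_surfaces <- function(source_mesh, target_mesh,
                              source_landmarks = NULL,
                              target_landmarks = NULL,
                              config = registration_config()) {
  cloud <- sample_point_cloud(source_mesh,
                              k = config$sample_size, seed = config$seed)
  init <- if (config$init_mode == "landmarks" &&
              !is.null(source_landmarks) && !is.null(target_landmarks))
    landmark_align(source_landmarks, target_landmarks)
  else if (config$init_mode == "identity") rigid_transform()
  else principal_axes_init(cloud, target_mesh, seed = config$seed)
  icp_register(cloud, target_mesh, init = init, config = config)
}
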