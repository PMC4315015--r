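# Shared internal helpers: seed derivation, grid bookkeeping, map containers.

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package funnels through one master seed; each stage
#' (subject simulation, ICA restarts, permutation tests, ...) derives its own
#' seed deterministically so that reruns reproduce every number while stages
#' remain decoupled.
#'
#' @param seed integer master seed.
#' @param stage character tag naming the consumer.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  # polynomial rolling hash; all arithmetic stays exact in doubles
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  h <- (h * 7919) %% 2147483647
  as.integer((h + abs(as.numeric(seed)) * 104729) %% 2147483647)
}

#' Define a voxel grid
#'
#' @param dim integer length-3 array dimensions (voxels per axis).
#' @param voxel_mm numeric length-3 voxel size in mm (or scalar, recycled).
#' @return a `scene_grid` list with elements `dim` and `voxel_mm`.
#' @export
scene_grid <- function(dim, voxel_mm = 3) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop("grid `dim` must be 3 positive integers")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("`voxel_mm` must be positive and finite")
  structure(list(dim = dim, voxel_mm = voxel_mm), class = "scene_grid")
}

#' Construct a single-subject 4D BOLD container
#'
#' @param data 4D numeric array `[x, y, z, t]`.
#' @param voxel_mm voxel size in mm (length 3 or scalar).
#' @param tr_s repetition time in seconds.
#' @param id subject identifier.
#' @param group group label, `"A"` or `"B"`.
#' @return a `subject_bold` object.
#' @export
subject_bold <- function(data, voxel_mm, tr_s, id = "sub-01", group = "A") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array [x, y, z, t]")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  stopifnot(is.finite(tr_s), tr_s > 0)
  group <- match.arg(group, c("A", "B"))
  structure(list(data = data, voxel_mm = voxel_mm, tr_s = tr_s,
                 id = as.character(id), group = group),
            class = "subject_bold")
}

#' @export
print.subject_bold <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<subject_bold> %s (group %s): %dx%dx%d voxels x %d volumes, voxel %s mm, TR %.3g s\n",
              x$id, x$group, d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_mm, 3), collapse = "x"), x$tr_s))
  invisible(x)
}

# Coerce map-like inputs (group_ica result, map_stack, D x V matrix over a
# mask, or 4D array [x,y,z,D]) to a common masked-matrix view.
as_map_matrix <- function(x, mask = NULL) {
  if (inherits(x, c("group_ica", "map_stack"))) {
    return(list(maps = x$maps, mask = x$mask, dim = x$dim,
                voxel_mm = x$voxel_mm))
  }
  if (is.array(x) && length(dim(x)) == 4L) {
    d <- dim(x)
    if (is.null(mask)) mask <- array(TRUE, d[1:3])
    m <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
    return(list(maps = t(m[as.vector(mask), , drop = FALSE]), mask = mask,
                dim = d[1:3], voxel_mm = NULL))
  }
  if (is.matrix(x)) {
    if (is.null(mask)) stop("a plain map matrix needs an explicit `mask`")
    return(list(maps = x, mask = mask, dim = dim(mask), voxel_mm = NULL))
  }
  stop("cannot interpret `", class(x)[1], "` as a stack of spatial maps")
}

#' Unmask a component-by-voxel matrix into a 4D array
#'
#' @param x a `group_ica` result, `map_stack`, or matrix (components x masked
#'   voxels; then `mask` is required).
#' @param mask logical 3D array when `x` is a plain matrix.
#' @return 4D array `[x, y, z, component]`, zero outside the mask.
#' @export
maps_to_array <- function(x, mask = NULL) {
  mm <- as_map_matrix(x, mask)
  d <- mm$dim
  out <- array(0, c(d, nrow(mm$maps)))
  flat <- matrix(0, prod(d), nrow(mm$maps))
  flat[as.vector(mm$mask), ] <- t(mm$maps)
  array(flat, c(d, nrow(mm$maps)))
}

# Subject 4D array -> (time x masked voxels) matrix.
subject_matrix <- function(subject, mask) {
  d <- dim(subject$data)
  m <- matrix(subject$data, nrow = prod(d[1:3]), ncol = d[4])
  t(m[as.vector(mask), , drop = FALSE])
}

#' Optimal one-to-one assignment between two sets of components
#'
#' Maximizes the total score over one-to-one pairings of rows to columns of a
#' score matrix. Exact (exhaustive over permutations) for up to 8 items on the
#' smaller side; greedy beyond that.
#'
#' @param score numeric matrix; `score[i, j]` is the benefit of pairing row
#'   component `i` with column component `j`.
#' @return data.frame with columns `row`, `col`, `score`, one row per pair
#'   (all rows matched if `nrow <= ncol`, else all columns).
#' @export
match_components <- function(score) {
  stopifnot(is.matrix(score), all(is.finite(score)))
  transposed <- FALSE
  if (nrow(score) > ncol(score)) { score <- t(score); transposed <- TRUE }
  k <- nrow(score); n <- ncol(score)
  if (k <= 8L && n <= 8L) {
    perms <- permutations_of(seq_len(n))
    best <- NULL; best_val <- -Inf
    for (p in perms) {
      sel <- p[seq_len(k)]
      v <- sum(score[cbind(seq_len(k), sel)])
      if (v > best_val) { best_val <- v; best <- sel }
    }
    assign <- best
  } else {
    assign <- integer(k)
    used <- logical(n)
    ord <- order(apply(score, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- which.max(ifelse(used, -Inf, score[i, ]))
      assign[i] <- j; used[j] <- TRUE
    }
  }
  out <- data.frame(row = seq_len(k), col = assign,
                    score = score[cbind(seq_len(k), assign)])
  if (transposed) out <- data.frame(row = out$col, col = out$row,
                                    score = out$score)
  out[order(out$row), , drop = FALSE]
}

# All permutations of a small vector (n! grows fast; callers keep n <= 8).
permutations_of <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- vector("list", 0L)
  for (i in seq_len(n)) {
    rest <- permutations_of(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}
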