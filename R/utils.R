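#' @importFrom stats runif rnorm rpois rexp optim nls lm coef mad sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single probability in [0, 1], got %s", name,
          deparse(substitute(x)))
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stopf("`%s` must be a single positive number", name)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stopf("`%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

#' Derive a per-stage seed from a global seed
#'
#' A single global seed fans out deterministically to one seed per named
#' pipeline stage so that any stage can be rerun in isolation and still
#' reproduce its draws. The derivation is plain 32-bit-safe arithmetic over
#' the stage name's character codes.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Half-neighborhood offsets (each undirected pair counted once).
.half_offsets <- function(ndim, connectivity) {
  if (ndim == 2L) {
    if (connectivity == 4L) return(list(c(1L, 0L), c(0L, 1L)))
    if (connectivity == 8L)
      return(list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L)))
  } else if (ndim == 3L) {
    if (connectivity == 6L)
      return(list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))
    if (connectivity == 26L) {
      offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
      offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
      # keep lexicographically positive half
      keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
        (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
      offs <- offs[keep, ]
      return(lapply(seq_len(nrow(offs)), function(i) as.integer(offs[i, ])))
    }
  }
  stopf("unsupported connectivity %d for %dD data", connectivity, ndim)
}

#' Label connected components of a binary array
#'
#' Works on 2D matrices and 3D arrays, with configurable connectivity
#' (4/8 in 2D, 6/26 in 3D) and optional periodic (wrap-around) boundaries
#' as used by the lattice self-assembly model.
#'
#' @param mask logical or 0/1 matrix or 3D array.
#' @param connectivity 4 or 8 (2D), 6 or 26 (3D). Defaults to 8 (2D) and
#'   26 (3D), the maximal neighborhoods.
#' @param periodic logical; treat opposite faces as adjacent.
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = NULL, periodic = FALSE) {
  dm <- dim(mask)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L)))
    stopf("`mask` must be a 2D matrix or 3D array")
  nd <- length(dm)
  connectivity <- as.integer(connectivity %||% if (nd == 2L) 8L else 26L)
  fg <- which(mask != 0)
  labels <- array(0L, dim = dm)
  if (length(fg) == 0L) return(labels)

  pos <- integer(prod(dm))
  pos[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dm)
  strides <- cumprod(c(1L, dm[-nd]))

  edges <- vector("list", 0L)
  for (off in .half_offsets(nd, connectivity)) {
    nb <- sweep(coords, 2L, off, `+`)
    if (periodic) {
      for (k in seq_len(nd)) nb[, k] <- ((nb[, k] - 1L) %% dm[k]) + 1L
      ok <- rep(TRUE, nrow(nb))
    } else {
      ok <- rep(TRUE, nrow(nb))
      for (k in seq_len(nd)) ok <- ok & nb[, k] >= 1L & nb[, k] <= dm[k]
    }
    if (!any(ok)) next
    lin <- as.integer(1 + (nb[ok, , drop = FALSE] - 1L) %*% strides)
    j <- pos[lin]
    hit <- j > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <-
        cbind(which(ok)[hit], j[hit])
  }

  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::make_graph(t(em), n = length(fg), directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  }
  memb <- igraph::components(g)$membership
  labels[fg] <- as.integer(memb)
  labels
}

# Sizes (in sites/voxels) of labeled components, as a named tabulation.
component_sizes <- function(labels) {
  v <- labels[labels > 0L]
  if (!length(v)) return(integer(0))
  tabulate(v)
}
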