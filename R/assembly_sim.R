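#' Parameters of the stochastic cluster self-assembly model
#'
#' The model evolves a binary occupancy lattice by three per-step events:
#' nucleation of new channels at isolated empty sites, growth of existing
#' clusters into adjacent empty sites, and removal of occupied sites. Steady
#' states of this process reproduce the exponential cluster-size
#' distributions observed for membrane channel clusters.
#'
#' @param p_nucleation probability per step that an empty site with no
#'   occupied 4-neighbor nucleates.
#' @param p_growth probability per step that an empty site 4-adjacent to an
#'   occupied site becomes occupied.
#' @param p_removal probability per step that an occupied site is vacated
#'   (applies to any occupied site, not only cluster edges).
#' @param grid_shape `c(rows, cols)` of the lattice.
#' @param max_steps cap on the number of update steps.
#' @param seed integer seed.
#' @return an object of class `assembly_params`.
#' @export
assembly_params <- function(p_nucleation, p_growth, p_removal,
                            grid_shape = c(512L, 512L),
                            max_steps = 5000L, seed = 1L) {
  assert_prob(p_nucleation, "p_nucleation")
  assert_prob(p_growth, "p_growth")
  assert_prob(p_removal, "p_removal")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stopf("`grid_shape` must be two dimensions >= 1")
  max_steps <- assert_count(max_steps, "max_steps", min = 1L)
  structure(list(p_nucleation = p_nucleation, p_growth = p_growth,
                 p_removal = p_removal, grid_shape = grid_shape,
                 max_steps = max_steps, seed = as.integer(seed)),
            class = "assembly_params")
}

#' Create a lattice state
#'
#' @param grid_shape `c(rows, cols)`, or pass `occupancy` directly.
#' @param occupancy optional 0/1 matrix to start from.
#' @return an object of class `lattice_state` with fields `occupancy`
#'   (logical matrix) and `step_index`.
#' @export
new_lattice <- function(grid_shape = NULL, occupancy = NULL) {
  if (is.null(occupancy)) {
    stopifnot(!is.null(grid_shape))
    occupancy <- matrix(FALSE, nrow = grid_shape[1], ncol = grid_shape[2])
  } else {
    occupancy <- matrix(as.logical(occupancy != 0), nrow = nrow(occupancy))
  }
  structure(list(occupancy = occupancy, step_index = 0L),
            class = "lattice_state")
}

# Periodic 4-neighborhood "any occupied neighbor" map.
.neighbor_any <- function(occ) {
  nr <- nrow(occ); nc <- ncol(occ)
  up    <- occ[c(2:nr, 1L), , drop = FALSE]
  down  <- occ[c(nr, seq_len(nr - 1L)), , drop = FALSE]
  left  <- occ[, c(2:nc, 1L), drop = FALSE]
  right <- occ[, c(nc, seq_len(nc - 1L)), drop = FALSE]
  up | down | left | right
}

#' One synchronous update of the self-assembly lattice
#'
#' All events are sampled from the state at the start of the step: occupied
#' sites are removed with `p_removal`; empty sites 4-adjacent to an occupied
#' site are filled with `p_growth` (growth takes precedence over nucleation
#' at such sites); empty sites with no occupied neighbor nucleate with
#' `p_nucleation`. Boundaries are periodic.
#'
#' @param state a `lattice_state` consistent with `params$grid_shape`.
#' @param params an [assembly_params()].
#' @return the updated `lattice_state` (step_index incremented). Draws come
#'   from the current RNG stream; seed control is the caller's.
#' @export
assembly_step <- function(state, params) {
  stopifnot(inherits(state, "lattice_state"),
            inherits(params, "assembly_params"))
  occ <- state$occupancy
  if (!all(dim(occ) == params$grid_shape))
    stopf("lattice shape %s does not match params grid_shape %s",
          paste(dim(occ), collapse = "x"),
          paste(params$grid_shape, collapse = "x"))
  n <- length(occ)
  adj <- .neighbor_any(occ)
  # one uniform draw per site: empty sites fill with p_growth (adjacent) or
  # p_nucleation (isolated); occupied sites are removed with p_removal.
  # The site sets are disjoint, so a shared draw keeps events independent.
  u <- runif(n)
  fill_p <- params$p_nucleation +
    (params$p_growth - params$p_nucleation) * adj
  fill <- !occ & (u < fill_p)
  keep <- occ & (u >= params$p_removal)
  state$occupancy <- keep | fill
  state$step_index <- state$step_index + 1L
  state
}

#' Cluster size distribution of a lattice state or of raw sizes
#'
#' @param x a `lattice_state` (sizes are 4-connected component site counts,
#'   periodic boundaries) or a numeric vector of sizes/volumes.
#' @param binwidth optional bin width for continuous sizes; integer lattice
#'   sizes are tabulated exactly when omitted.
#' @return a `size_distribution` data.frame with columns `size`, `count`,
#'   `relative_frequency` (summing to 1).
#' @export
size_distribution <- function(x, binwidth = NULL) {
  if (inherits(x, "lattice_state")) {
    labels <- label_components(x$occupancy * 1L, connectivity = 4L,
                               periodic = TRUE)
    sizes <- component_sizes(labels)
    if (!length(sizes))
      return(structure(data.frame(size = numeric(0), count = numeric(0),
                                  relative_frequency = numeric(0)),
                       class = c("size_distribution", "data.frame")))
    tb <- table(sizes)
    d <- data.frame(size = as.numeric(names(tb)), count = as.numeric(tb))
  } else {
    x <- as.numeric(x)
    if (is.null(binwidth)) {
      tb <- table(x)
      d <- data.frame(size = as.numeric(names(tb)), count = as.numeric(tb))
    } else {
      assert_positive(binwidth, "binwidth")
      # half-open bins [k*w, (k+1)*w), reported at bin centers
      idx <- floor(x / binwidth)
      tb <- table(idx)
      d <- data.frame(size = (as.numeric(names(tb)) + 0.5) * binwidth,
                      count = as.numeric(tb))
    }
  }
  d$relative_frequency <- d$count / sum(d$count)
  structure(d, class = c("size_distribution", "data.frame"))
}

#' Run the self-assembly model to steady state
#'
#' Iterates [assembly_step()] from an empty (or supplied) lattice until a
#' stationarity criterion on total occupancy holds or `max_steps` is reached.
#' The criterion: consecutive 500-step block means of total occupancy differ
#' by a relative amount below `rel_tol` for `consecutive` blocks in a row.
#' The default tolerance (2%) sits just above the stationary fluctuation of
#' block means on grids of a few hundred sites occupied; tighter tolerances
#' fall below that noise floor and never trigger.
#'
#' @param params an [assembly_params()]; `params$seed` controls all draws.
#' @param init optional starting `lattice_state`.
#' @param window block length for the occupancy moving average.
#' @param rel_tol relative-change tolerance between block means.
#' @param consecutive number of consecutive quiet blocks required.
#' @return a list with `state` (final `lattice_state`), `distribution`
#'   (a `size_distribution`), `converged` flag, and `occupancy_trace`
#'   (total occupied sites per step).
#' @export
run_to_steady_state <- function(params, init = NULL, window = 500L,
                                rel_tol = 0.02, consecutive = 3L) {
  stopifnot(inherits(params, "assembly_params"))
  state <- init %||% new_lattice(params$grid_shape)
  occ_trace <- numeric(params$max_steps)
  converged <- FALSE
  with_seed(params$seed, {
    prev_mean <- NA_real_
    quiet <- 0L
    for (s in seq_len(params$max_steps)) {
      state <- assembly_step(state, params)
      occ_trace[s] <- sum(state$occupancy)
      if (s %% window == 0L) {
        m <- mean(occ_trace[(s - window + 1L):s])
        if (!is.na(prev_mean)) {
          rel <- abs(m - prev_mean) / max(prev_mean, 1)
          quiet <- if (rel < rel_tol) quiet + 1L else 0L
        }
        prev_mean <- m
        if (quiet >= consecutive) {
          converged <- TRUE
          occ_trace <- occ_trace[seq_len(s)]
          break
        }
      }
    }
  })
  if (!converged)
    occ_trace <- occ_trace[seq_len(state$step_index)]
  list(state = state, distribution = size_distribution(state),
       converged = converged, occupancy_trace = occ_trace)
}

#' Squared distance between two size distributions
#'
#' Sum of squared differences of relative frequencies over the union of the
#' two supports (absent sizes count as frequency 0), so that grids and cells
#' of different sizes are comparable.
#'
#' @param a,b `size_distribution` objects.
#' @return a non-negative number; 0 iff the distributions are identical.
#' @export
dist_size_distributions <- function(a, b) {
  sizes <- sort(unique(c(a$size, b$size)))
  fa <- a$relative_frequency[match(sizes, a$size)]
  fb <- b$relative_frequency[match(sizes, b$size)]
  fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
  sum((fa - fb)^2)
}

#' Fit assembly parameters to an observed size distribution by grid search
#'
#' Simulates each candidate parameter set with several replicate seeds,
#' averages the steady-state relative-frequency distributions, and returns
#' the grid point minimizing [dist_size_distributions()] to the observed
#' distribution.
#'
#' @param observed a `size_distribution` (relative frequencies).
#' @param search data.frame grid with columns `p_nucleation`, `p_growth`,
#'   `p_removal`.
#' @param grid_shape lattice size used for the candidate simulations.
#' @param steps fixed number of update steps per simulation (a burn-in long
#'   enough to reach the stationary regime at the grid size used).
#' @param replicates number of replicate seeds averaged per grid point.
#' @param seed base seed; replicate r of grid point g uses a seed derived
#'   from it.
#' @return a list with `params` (the best [assembly_params()]), `distance`,
#'   and `table` (the full grid with distances).
#' @export
fit_params <- function(observed, search, grid_shape = c(128L, 128L),
                       steps = 1500L, replicates = 3L, seed = 1L) {
  stopifnot(inherits(observed, "size_distribution"))
  search <- as.data.frame(search)
  if (nrow(search) == 0L) stopf("`search` grid is empty")
  need <- c("p_nucleation", "p_growth", "p_removal")
  if (!all(need %in% names(search)))
    stopf("`search` must have columns %s", paste(need, collapse = ", "))

  dists <- vapply(seq_len(nrow(search)), function(g) {
    reps <- lapply(seq_len(replicates), function(r) {
      pars <- assembly_params(search$p_nucleation[g], search$p_growth[g],
                              search$p_removal[g], grid_shape = grid_shape,
                              max_steps = steps,
                              seed = derive_seed(seed, sprintf("fit-%d-%d", g, r)))
      # fixed-length burn-in: disable the early-stop criterion
      run_to_steady_state(pars, window = steps + 1L)$distribution
    })
    sizes <- sort(unique(unlist(lapply(reps, `[[`, "size"))))
    fmat <- vapply(reps, function(d) {
      f <- d$relative_frequency[match(sizes, d$size)]
      f[is.na(f)] <- 0
      f
    }, numeric(length(sizes)))
    avg <- structure(data.frame(size = sizes,
                                count = rowMeans(as.matrix(fmat)),
                                relative_frequency = rowMeans(as.matrix(fmat))),
                     class = c("size_distribution", "data.frame"))
    dist_size_distributions(observed, avg)
  }, numeric(1))

  best <- which.min(dists)
  out <- search
  out$distance <- dists
  list(params = assembly_params(search$p_nucleation[best],
                                search$p_growth[best],
                                search$p_removal[best],
                                grid_shape = grid_shape,
                                max_steps = steps, seed = seed),
       distance = dists[best], table = out)
}
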