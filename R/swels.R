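# Sliding-Window Energy Layer Sorting (SWELS). Step-and-shoot arcs pay ~6 s
# for every low-to-high energy switch but only ~0.8 s going down; SWELS
# reorders the one-energy-per-control-point sequence toward descending order,
# while guaranteeing that no layer ends up farther from its planned gantry
# position than the window allows.

#' SWELS parameters
#'
#' The window size is expressed in degrees of arc; dividing by the plan
#' resolution gives the window capacity, the maximum number of consecutive
#' control points sorted together. A 15 degree window over a 2.8 degree
#' resolution arc holds at most five control points. Studied window sizes are
#' 10, 25 and 40 degrees.
#'
#' @param window_deg Window size, degrees (> 0).
#' @param resolution_deg Arc control-point spacing, degrees (> 0).
#' @return A list of class `swels_params`.
#' @export
swels_params <- function(window_deg, resolution_deg) {
  if (!is.finite(window_deg) || window_deg <= 0)
    stop("window_deg must be positive", call. = FALSE)
  if (!is.finite(resolution_deg) || resolution_deg <= 0)
    stop("resolution_deg must be positive", call. = FALSE)
  structure(list(window_deg = window_deg, resolution_deg = resolution_deg),
            class = "swels_params")
}

#' Window capacity in control points
#'
#' @param params A [swels_params()].
#' @return `floor(window_deg / resolution_deg)`; values below 2 make sorting
#'   a no-op.
#' @export
window_capacity <- function(params) {
  max(1L, as.integer(floor(params$window_deg / params$resolution_deg)))
}

#' Sliding-window descending sort order of an energy sequence
#'
#' The core SWELS pass over a numeric energy sequence. A window grows from a
#' single control point to the given capacity, re-sorting its contents in
#' descending energy order at every step, then slides one index at a time.
#' When, after a slide, the energy entering at the window's last index exceeds
#' the energy at its first index, the window jumps so that the last index
#' becomes the new first index and regrows from there (the stop condition).
#' One left-to-right pass is made; there is no iteration to convergence.
#'
#' Each layer additionally carries a displacement deadline: a layer is never
#' placed more than `capacity - 1` positions from where it started, so the
#' within-window sort pins a layer in place once further right-movement would
#' exceed the bound. Ties (equal energies) are kept in their current order and
#' never trigger the jump condition.
#'
#' @param energies Numeric vector of per-control-point energies.
#' @param capacity Window capacity in control points (see [window_capacity()]).
#' @return An integer permutation `ord` such that `energies[ord]` is the
#'   sorted sequence; position `i` of the output takes the layer originally at
#'   `ord[i]`.
#' @export
swels_sort_order <- function(energies, capacity) {
  n <- length(energies)
  k <- as.integer(capacity)
  if (k < 2 || n < 2) return(seq_len(n))

  # Constrained descending sort of arr[s..j]: slot by slot, place the layer
  # whose displacement deadline has arrived, otherwise the highest energy.
  sortwin <- function(arr, s, j) {
    remaining <- arr[s:j]
    res <- integer(j - s + 1L)
    for (p in s:j) {
      must <- remaining[remaining + k - 1L <= p]
      pick <- if (length(must)) must[which.max(energies[must])]
              else remaining[which.max(energies[remaining])]
      res[p - s + 1L] <- pick
      remaining <- remaining[remaining != pick]
    }
    arr[s:j] <- res
    arr
  }

  arr <- seq_len(n)
  s <- 1L; j <- 1L
  repeat {
    if (j == n) { arr <- sortwin(arr, s, j); break }
    if (j - s + 1L < k) {          # grow to capacity
      j <- j + 1L
      arr <- sortwin(arr, s, j)
    } else {                        # slide by one
      s <- s + 1L; j <- j + 1L
      if (energies[arr[j]] > energies[arr[s]]) s <- j  # stop condition: jump
      else arr <- sortwin(arr, s, j)
    }
  }
  arr
}

#' Sort a plan's energy layers with SWELS
#'
#' Applies [swels_sort_order()] to the plan's energy sequence and remaps whole
#' energy layers (energy, spots and trimmer configurations together) onto the
#' plan's fixed gantry positions. The multiset of energies is preserved; only
#' their assignment to gantry angles changes, which effectively applies small
#' beam-angle changes to previously optimized layers. Spot lattices are not
#' regenerated here; the CSG pipeline does that before reoptimizing weights.
#'
#' @param plan An `arc_plan`.
#' @param params A [swels_params()]; its `resolution_deg` should match the
#'   plan's.
#' @return The sorted `arc_plan`. Attribute `"swels_order"` records the
#'   permutation applied.
#' @export
sort_energies <- function(plan, params) {
  cps <- plan$control_points
  if (length(cps) < 2) return(plan)
  e <- plan_energies(plan)
  ord <- swels_sort_order(e, window_capacity(params))
  g <- gantry_angles(plan)
  new_cps <- vector("list", length(cps))
  for (i in seq_along(cps)) {
    cp <- cps[[ord[i]]]
    cp$gantry_deg <- g[i]
    cp$index <- i - 1L
    new_cps[[i]] <- cp
  }
  plan$control_points <- new_cps
  attr(plan, "swels_order") <- ord
  plan
}

#' Count low-to-high energy transitions
#'
#' Up-jumps are the slow (~6 s) energy switches SWELS tries to eliminate.
#' Equal consecutive energies count as neither up nor down.
#'
#' @param x An `arc_plan` or a numeric energy sequence.
#' @return Number of consecutive pairs whose energy increases.
#' @export
count_upjumps <- function(x) {
  e <- if (inherits(x, "arc_plan")) plan_energies(x) else as.numeric(x)
  if (length(e) < 2) return(0L)
  sum(diff(e) > 0)
}
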