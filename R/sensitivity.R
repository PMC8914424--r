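# Deterministic sensitivity analysis: preference surface over the two
# re-intervention probabilities and closed-form cost-equivalence thresholds.

#' Grid specification for two-way sensitivity analysis
#'
#' @param p_min,p_max Closed probability interval per axis (defaults
#'   \[0, 0.5\], the published evaluation range).
#' @param step Grid step (default 0.01). Both endpoints are always included.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(p_min = 0, p_max = 0.5, step = 0.01) {
  if (!is.numeric(p_min) || !is.numeric(p_max) || p_min < 0 || p_max > 1 ||
      p_min > p_max) {
    abort("need 0 <= p_min <= p_max <= 1.")
  }
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    abort("`step` must be positive.")
  }
  list(p_min = p_min, p_max = p_max, step = step)
}

# Axis values for a grid spec; endpoints always present.
grid_points <- function(grid) {
  pts <- seq(grid$p_min, grid$p_max, by = grid$step)
  if (pts[length(pts)] < grid$p_max - 1e-12) pts <- c(pts, grid$p_max)
  pts
}

#' Two-way preference surface
#'
#' Evaluates the base-case closed form (no sampling) at every node of a grid
#' over the two strategies' re-intervention probabilities, recording each
#' strategy's expected cost, the savings of the first strategy, and which
#' strategy is strictly preferred. Nodes where the costs differ by less than
#' one cent are ties. The one-way analyses are the two axis-aligned slices of
#' this surface through the base-case point.
#'
#' @param model A [decision_model()].
#' @param grid A [grid_spec()] (applied to both axes).
#' @return A `preference_surface` tibble with columns `p_<first>`,
#'   `p_<second>`, `cost_<first>`, `cost_<second>`, `savings`, `preferred`.
#' @export
#' @examples
#' surf <- preference_surface(us_medicare_model(), grid_spec(0, 0.5, 0.05))
#' table(surf$preferred)
preference_surface <- function(model, grid = grid_spec()) {
  stopifnot(inherits(model, "decision_model"))
  pts <- grid_points(grid)
  if (length(pts) == 0) abort("grid is empty.")
  nm <- tolower(names(model$strategies))
  prof <- purrr::map(model$strategies, "profile")
  nodes <- tidyr::expand_grid(p_a = pts, p_b = pts)
  cost_a <- expected_cost(prof[[1]], nodes$p_a)
  cost_b <- expected_cost(prof[[2]], nodes$p_b)
  savings <- cost_b - cost_a
  preferred <- dplyr::case_when(
    savings > TIE_TOLERANCE ~ names(model$strategies)[1],
    savings < -TIE_TOLERANCE ~ names(model$strategies)[2],
    TRUE ~ "tie"
  )
  out <- tibble::tibble(
    p_a = nodes$p_a, p_b = nodes$p_b,
    cost_a = cost_a, cost_b = cost_b,
    savings = savings, preferred = preferred
  )
  names(out)[1:4] <- c(paste0("p_", nm), paste0("cost_", nm))
  structure(out,
            strategies = names(model$strategies), grid = grid, model = model,
            class = c("preference_surface", class(out)))
}

#' @rdname preference_surface
#' @param object A `preference_surface`.
#' @param ... Unused.
#' @method autoplot preference_surface
#' @export
autoplot.preference_surface <- function(object, ...) {
  nm <- attr(object, "strategies")
  axes <- paste0("p_", tolower(nm))
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[axes[1]]],
                                       y = .data[[axes[2]]],
                                       fill = .data$preferred)) +
    ggplot2::geom_raster() +
    ggplot2::labs(
      x = paste("Re-intervention probability,", nm[1]),
      y = paste("Re-intervention probability,", nm[2]),
      fill = "Preferred",
      title = "Preferred strategy by re-intervention probabilities"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Closed-form cost-equivalence threshold
#'
#' Solves for the re-intervention probability `p*` of the varied strategy at
#' which its expected cost equals the other strategy's expected cost at a
#' fixed probability: `C_init,v + p* C_reint,v = C_init,o + p_o C_reint,o`.
#'
#' @param model A [decision_model()].
#' @param vary Name of the strategy whose probability is varied.
#' @param fixed_p Probability at which the other strategy is held (defaults
#'   to its base-case point estimate).
#' @return `p*` as a single number, or `NA` when no crossing exists in
#'   \[0, 1\] (including the degenerate zero re-intervention-cost case with
#'   unequal fixed costs).
#' @export
#' @examples
#' equal_cost_threshold(us_medicare_model(), vary = "EUS-BD") # ~0.925
equal_cost_threshold <- function(model, vary, fixed_p = NULL) {
  stopifnot(inherits(model, "decision_model"))
  idx <- match(vary, names(model$strategies))
  if (is.na(idx)) {
    abort(sprintf("unknown strategy '%s'.", vary))
  }
  varied <- model$strategies[[idx]]$profile
  other <- model$strategies[[setdiff(1:2, idx)]]
  fixed_p <- fixed_p %||% other$evidence$point_estimate
  check_prob(fixed_p, "fixed_p")
  target <- expected_cost(other$profile, fixed_p)
  if (varied$reintervention_cost == 0) {
    # flat cost in p: equal everywhere or nowhere
    if (abs(varied$initial_cost - target) < TIE_TOLERANCE) return(0)
    return(NA_real_)
  }
  p_star <- (target - varied$initial_cost) / varied$reintervention_cost
  if (p_star < 0 || p_star > 1) NA_real_ else p_star
}

#' Largest square region where the first strategy is preferred
#'
#' Finds the largest bound `b` (on the grid defined by `step`) such that the
#' first strategy is strictly preferred at every node of the square
#' \[0, b\]^2 of re-intervention probabilities. Because both cost forms are
#' affine, the binding corner is the varied strategy at `b` against the other
#' strategy at 0, so the bound is resolved by direct evaluation along the
#' diagonal corner.
#'
#' @param model A [decision_model()].
#' @param step Grid resolution of the returned bound (default 0.01); use
#'   `exact = TRUE` for the closed-form bound.
#' @param exact Return the exact crossing point instead of a grid-resolved
#'   bound.
#' @return A probability bound in \[0, 1\].
#' @export
#' @examples
#' favored_region_bound(us_medicare_model())               # 0.84
#' favored_region_bound(us_medicare_model(), exact = TRUE) # ~0.845
favored_region_bound <- function(model, step = 0.01, exact = FALSE) {
  stopifnot(inherits(model, "decision_model"))
  first <- model$strategies[[1]]$profile
  second <- model$strategies[[2]]$profile
  # worst case on [0, b]^2 for the first strategy: own p at b, rival p at 0
  margin <- function(b) {
    expected_cost(second, 0) - expected_cost(first, b)
  }
  if (margin(0) <= TIE_TOLERANCE) return(0)
  if (exact) {
    if (first$reintervention_cost == 0) return(1)
    return(min(1, (second$initial_cost - first$initial_cost) /
                  first$reintervention_cost))
  }
  pts <- seq(0, 1, by = step)
  ok <- margin(pts) > TIE_TOLERANCE
  pts[max(which(cumsum(!ok) == 0))]
}
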