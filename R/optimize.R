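# Regularization-parameter sweeps: solve the montage across a lambda grid
# (reusing one assembled system), score each solution by median residual
# and scale MAD, and select parameters meeting the targets.

default_lambda_grid <- function() {
  data.frame(lambda_translation = 1e-5,
             lambda_linear = 10^seq(-2, 6))
}

# Metrics of a solution without writing back into a collection.
solution_metrics <- function(sys, sol, matches) {
  tfs <- extract_tile_transforms(sys, sol)
  res <- numeric(0)
  pair_means <- numeric(0)
  for (e in matches$entries) {
    if (is.null(tfs[[e$p_id]]) || is.null(tfs[[e$q_id]]) || nrow(e$P) == 0) next
    d <- tf_apply(tfs[[e$p_id]], e$P) - tf_apply(tfs[[e$q_id]], e$Q)
    pair_means <- c(pair_means, mean(sqrt(rowSums(d^2))))
  }
  mad <- scales_mad(tfs)
  list(median_residual = median(pair_means), mad = mad, transforms = tfs)
}

#' Sweep montage regularization parameters
#'
#' Solves the montage at every point of a lambda grid (the constraint
#' matrix is assembled once and only the regularization diagonal changes),
#' computes the median pair residual and the x/y scale MAD of each
#' solution, and accepts those meeting the residual and MAD targets. The
#' chosen point is the accepted one with the smallest residual, ties
#' broken by smaller MAD_x + MAD_y, then larger lambda_linear.
#'
#' @param coll Section [tile_collection()] (lens-corrected or later).
#' @param matches Same-section [point_match_set()].
#' @param z Section index.
#' @param lambda_grid Data frame with columns `lambda_translation`,
#'   `lambda_linear` (relative factors; default log-spaced
#'   `lambda_linear` 1e-2..1e6 with soft translation term).
#' @param residual_max Residual target in px.
#' @param mad_max MAD target; length 1 or 2 (x, y).
#' @param opts Base [solve_options()].
#' @return List: `table` (sweep table with metrics and accepted flag),
#'   `accepted` (row indices), `chosen` (row index or NA), `chosen_opts`,
#'   `solution` (metrics of the chosen solution, incl. transforms).
#' @export
sweep_lambda <- function(coll, matches, z = NULL,
                         lambda_grid = default_lambda_grid(),
                         residual_max = 5, mad_max = 0.005,
                         opts = solve_options()) {
  if (nrow(lambda_grid) == 0) stop("lambda_grid must be nonempty")
  if (is.null(z)) z <- coll$sections[1]
  mad_max <- rep(mad_max, length.out = 2)
  sec_ids <- names(coll$tiles)[vapply(coll$tiles, function(t) t$z == z,
                                      logical(1))]
  sec <- coll; sec$tiles <- coll$tiles[sec_ids]
  sys <- assemble_system(matches, sec, opts)
  tab <- lambda_grid
  tab$median_residual <- NA_real_
  tab$MAD_x <- NA_real_; tab$MAD_y <- NA_real_
  sols <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    o <- opts
    o$lambda_translation <- tab$lambda_translation[i]
    o$lambda_linear <- tab$lambda_linear[i]
    sys_i <- set_system_lambda(sys, o)
    sol <- solve_regularized(sys_i)
    met <- solution_metrics(sys_i, sol, matches)
    tab$median_residual[i] <- met$median_residual
    tab$MAD_x[i] <- met$mad[["MAD_x"]]
    tab$MAD_y[i] <- met$mad[["MAD_y"]]
    sols[[i]] <- met
  }
  tab$accepted <- tab$median_residual <= residual_max &
    tab$MAD_x <= mad_max[1] & tab$MAD_y <= mad_max[2]
  accepted <- which(tab$accepted)
  chosen <- NA_integer_
  if (length(accepted) > 0) {
    ord <- order(tab$median_residual[accepted],
                 tab$MAD_x[accepted] + tab$MAD_y[accepted],
                 -tab$lambda_linear[accepted])
    chosen <- accepted[ord[1]]
  }
  chosen_opts <- if (!is.na(chosen)) {
    o <- opts
    o$lambda_translation <- tab$lambda_translation[chosen]
    o$lambda_linear <- tab$lambda_linear[chosen]
    o
  } else NULL
  list(table = tab, accepted = accepted, chosen = chosen,
       chosen_opts = chosen_opts,
       solution = if (!is.na(chosen)) sols[[chosen]] else NULL)
}

#' Sweep with iterative criterion relaxation
#'
#' Runs [sweep_lambda()] at the strictest MAD criteria and, if nothing is
#' accepted, advances through a relaxation schedule (default
#' `(0.005, 0.005)` then `(0.006, 0.007)` in x and y) until a candidate
#' montage appears or the schedule is exhausted, recording the level that
#' succeeded. An exhausted schedule returns a failure report carrying the
#' best-achieved metrics; such montages remain usable at the caller's
#' discretion.
#'
#' @inheritParams sweep_lambda
#' @param schedule List of length-2 numeric vectors `(mad_x, mad_y)`, from
#'   strictest to the predetermined boundary.
#' @return As [sweep_lambda()], plus `level` (1-based index into the
#'   schedule, NA on failure) and `criteria` used.
#' @export
relax_and_select <- function(coll, matches, z = NULL,
                             lambda_grid = default_lambda_grid(),
                             residual_max = 5,
                             schedule = list(c(0.005, 0.005),
                                             c(0.006, 0.007)),
                             opts = solve_options()) {
  best <- NULL
  for (lev in seq_along(schedule)) {
    sw <- sweep_lambda(coll, matches, z, lambda_grid, residual_max,
                       mad_max = schedule[[lev]], opts = opts)
    if (is.null(best)) best <- sw
    if (!is.na(sw$chosen)) {
      sw$level <- lev
      sw$criteria <- schedule[[lev]]
      return(sw)
    }
  }
  best$level <- NA_integer_
  best$criteria <- schedule[[length(schedule)]]
  best$failure <- TRUE
  i_best <- which.min(best$table$median_residual)
  best$best_achieved <- best$table[i_best, , drop = FALSE]
  best
}
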