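# Fitting of isotherm parameters. Residuals are taken in moisture content at
# the table's water activities (the way sorption isotherms are plotted), so
# every objective evaluation inverts the isotherm once per row.

#' Validate a sorption table
#'
#' A sorption table holds equilibrium points `(aw, mc_wb, temp_K, direction)`
#' with `aw` strictly inside (0, 1) and rows sorted by `aw`.
#'
#' @param x A data frame with columns `aw`, `mc_wb`, `temp_K` and optionally
#'   `direction` (`"sorption"` or `"desorption"`, default desorption — the
#'   branch that governs drying).
#' @return A `sorption_table` tibble.
#' @export
as_sorption_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("aw", "mc_wb", "temp_K")
  if (!all(need %in% names(x))) {
    abort(sprintf("A sorption table needs columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (!"direction" %in% names(x)) x$direction <- "desorption"
  if (any(x$aw <= 0 | x$aw >= 1)) abort("`aw` must lie strictly within (0, 1).")
  if (any(x$mc_wb <= 0 | x$mc_wb >= 1)) abort("`mc_wb` must lie in (0, 1).")
  x <- dplyr::arrange(x, .data$aw)
  class(x) <- c("sorption_table", class(x))
  x
}

# rows usable for the rubbery-state chi fit: temperature above the mixture
# glass transition at the observed moisture content
.rubbery_rows <- function(table, ck) {
  tg <- .tg_ck(table$mc_wb, ck)$T_g
  table$temp_K > tg
}

#' Fit the Flory-Huggins interaction parameter to sorption data
#'
#' Least-squares fit of `chi_ws` on the rows of a sorption table that lie
#' above the glass transition (where the bare Flory-Huggins model applies).
#' Residuals are differences in equilibrium moisture content at the measured
#' water activities. Deterministic given the data.
#'
#' @param table A [as_sorption_table()] data frame.
#' @param comp A [seed_composition()] (dry-matter recipe).
#' @param params An [isotherm_params()] set; `chi_ws` is the free parameter,
#'   everything else is held fixed.
#' @param interval Search interval for `chi_ws`.
#' @return A `chi_fit` object with elements `chi_ws`, `se`, `data`,
#'   `fitted`, `n`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_chi <- function(table, comp = default_composition(),
                    params = isotherm_params(), interval = c(0.01, 5)) {
  table <- as_sorption_table(table)
  use <- .rubbery_rows(table, params$ck)
  if (sum(!use) > 0) {
    inform(sprintf("fit_chi(): dropping %d glassy-state row(s); fitting on %d rubbery row(s).",
                   sum(!use), sum(use)))
  }
  tab <- table[use, , drop = FALSE]
  if (nrow(tab) < 3) {
    abort(sprintf("fit_chi() needs >= 3 rows above the glass transition (got %d).",
                  nrow(tab)))
  }
  pred <- function(chi) {
    p <- params; p$chi_ws <- chi
    vapply(seq_len(nrow(tab)),
           function(i) equilibrium_moisture(tab$aw[i], tab$temp_K[i], comp, p),
           numeric(1))
  }
  obj <- function(chi) sum((pred(chi) - tab$mc_wb)^2)
  opt <- optimize(obj, interval = interval, tol = 1e-10)
  chi_hat <- opt$minimum
  fitted <- pred(chi_hat)
  resid <- tab$mc_wb - fitted
  h <- 1e-6 * max(1, abs(chi_hat))
  jac <- (pred(chi_hat + h) - pred(chi_hat - h)) / (2 * h)
  dof <- max(1, nrow(tab) - 1)
  sigma2 <- sum(resid^2) / dof
  se <- if (sum(jac^2) > 0) sqrt(sigma2 / sum(jac^2)) else NA_real_
  structure(
    list(chi_ws = chi_hat, se = se, rss = sum(resid^2), n = nrow(tab),
         n_dropped = sum(!use),
         data = tibble::tibble(aw = tab$aw, temp_K = tab$temp_K,
                               mc_wb = tab$mc_wb, fitted = fitted,
                               residual = resid),
         comp = comp, params = params),
    class = "chi_fit"
  )
}

#' Fit the glassy bulk modulus to final drying moisture contents
#'
#' Least-squares fit of the Leibler-Sekimoto modulus `K_g` against observed
#' final moisture contents of drying runs, with all other isotherm parameters
#' fixed. Points must lie in the glassy region (temperature below the glass
#' transition at the observed moisture); rubbery points carry no information
#' about `K_g` and are dropped with a message.
#'
#' @param points A data frame with columns `rh` (water activity of the drying
#'   air), `temp_K` and `mc_wb` (observed final moisture, wet basis).
#' @param comp A [seed_composition()].
#' @param params An [isotherm_params()] set; forced to model `"FH_LS"`.
#' @param interval Search interval for `log10(K_g)`.
#' @return A `kg_fit` object with elements `K_g`, `rss`, `n`, `data`.
#' @export
fit_kg <- function(points, comp = default_composition(),
                   params = isotherm_params(model = "FH_LS"),
                   interval = c(6, 12)) {
  points <- tibble::as_tibble(points)
  need <- c("rh", "temp_K", "mc_wb")
  if (!all(need %in% names(points))) {
    abort(sprintf("`points` needs columns %s.", paste(need, collapse = ", ")))
  }
  params$model <- "FH_LS"
  glassy <- points$temp_K < .tg_ck(points$mc_wb, params$ck)$T_g
  if (!any(glassy)) {
    abort("fit_kg(): all points are in the rubbery state; K_g is unidentifiable.")
  }
  if (any(!glassy)) {
    inform(sprintf("fit_kg(): dropping %d rubbery point(s).", sum(!glassy)))
  }
  pts <- points[glassy, , drop = FALSE]
  pred <- function(log10kg) {
    p <- params; p$K_g <- 10^log10kg
    vapply(seq_len(nrow(pts)),
           function(i) equilibrium_moisture(pts$rh[i], pts$temp_K[i], comp, p),
           numeric(1))
  }
  obj <- function(lk) sum((pred(lk) - pts$mc_wb)^2)
  opt <- optimize(obj, interval = interval, tol = 1e-11)
  kg_hat <- 10^opt$minimum
  if (kg_hat <= 0) abort("fit_kg(): optimum K_g is not positive.")
  fitted <- pred(opt$minimum)
  structure(
    list(K_g = kg_hat, rss = sum((fitted - pts$mc_wb)^2), n = nrow(pts),
         n_dropped = sum(!glassy),
         data = tibble::tibble(rh = pts$rh, temp_K = pts$temp_K,
                               mc_wb = pts$mc_wb, fitted = fitted),
         comp = comp, params = params),
    class = "kg_fit"
  )
}

#' @export
print.chi_fit <- function(x, ...) {
  cat(sprintf("<chi_fit> chi_ws = %.6f (se %.2g), n = %d, RSS = %.3g\n",
              x$chi_ws, x$se, x$n, x$rss))
  invisible(x)
}

#' @export
print.kg_fit <- function(x, ...) {
  cat(sprintf("<kg_fit> K_g = %.4g Pa, n = %d, RSS = %.3g\n",
              x$K_g, x$n, x$rss))
  invisible(x)
}

#' @export
tidy.chi_fit <- function(x, ...) {
  tibble::tibble(term = "chi_ws", estimate = x$chi_ws, std.error = x$se)
}

#' @export
glance.chi_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, n_dropped = x$n_dropped)
}

#' @export
tidy.kg_fit <- function(x, ...) {
  tibble::tibble(term = "K_g", estimate = x$K_g, std.error = NA_real_)
}

#' @export
glance.kg_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, n_dropped = x$n_dropped)
}
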