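#' Percent error between experimental and modelled drying curves
#'
#' `PE = 100/n * sum |MC_exp - MC_model| / MC_model`, the mean absolute
#' relative deviation with the model value in the denominator. The model
#' curve (typically densely sampled) is linearly interpolated to the
#' experimental timestamps. A PE below 10 % is conventionally read as high
#' accuracy.
#'
#' @param exp_curve A data frame with columns `time_s`, `mc_wb`
#'   (experimental).
#' @param model_curve A data frame with columns `time_s`, `mc_wb` (model).
#' @param exclude_times Timestamps (s) to drop from the comparison, e.g. a
#'   0 % RH endpoint that would dominate the statistic.
#' @return A `pe_result` list with elements `PE` (percent), `n` and a
#'   `residuals` tibble `(time_s, mc_exp, mc_model, rel_abs_dev)`. Supports
#'   [tidy()] and [glance()].
#' @examples
#' exp <- tibble::tibble(time_s = c(0, 3600), mc_wb = c(0.22, 0.11))
#' mod <- tibble::tibble(time_s = c(0, 3600), mc_wb = c(0.20, 0.10))
#' percent_error(exp, mod)$PE  # 10
#' @export
percent_error <- function(exp_curve, model_curve, exclude_times = NULL) {
  exp_curve <- tibble::as_tibble(exp_curve)
  model_curve <- tibble::as_tibble(model_curve)
  for (nm in list(exp_curve, model_curve)) {
    if (!all(c("time_s", "mc_wb") %in% names(nm))) {
      abort("Curves need columns `time_s` and `mc_wb`.")
    }
  }
  if (!is.null(exclude_times)) {
    keep <- !vapply(exp_curve$time_s,
                    function(t) any(abs(t - exclude_times) < 1e-9), logical(1))
    exp_curve <- exp_curve[keep, , drop = FALSE]
  }
  if (nrow(exp_curve) < 1) abort("No experimental points left to compare.")
  span <- range(model_curve$time_s)
  out_of_span <- exp_curve$time_s < span[1] - 1e-9 |
    exp_curve$time_s > span[2] + 1e-9
  if (any(out_of_span)) {
    abort(sprintf(
      "Experimental time(s) outside the simulated span [%g, %g] s: %s",
      span[1], span[2],
      paste(utils::head(exp_curve$time_s[out_of_span], 5), collapse = ", ")
    ))
  }
  mc_model <- approx(model_curve$time_s, model_curve$mc_wb,
                     xout = exp_curve$time_s, ties = "ordered")$y
  if (any(mc_model == 0)) {
    abort("Model moisture content is zero at a compared time; PE undefined.")
  }
  rel <- abs(exp_curve$mc_wb - mc_model) / mc_model
  structure(
    list(PE = 100 * mean(rel), n = length(rel),
         residuals = tibble::tibble(time_s = exp_curve$time_s,
                                    mc_exp = exp_curve$mc_wb,
                                    mc_model = mc_model,
                                    rel_abs_dev = rel)),
    class = "pe_result"
  )
}

#' @export
print.pe_result <- function(x, ...) {
  cat(sprintf("<pe_result> PE = %.3f %% over n = %d points\n", x$PE, x$n))
  invisible(x)
}

#' @export
tidy.pe_result <- function(x, ...) x$residuals

#' @export
glance.pe_result <- function(x, ...) {
  tibble::tibble(PE = x$PE, n = x$n)
}

#' Run a scenario and score it against an experimental curve
#'
#' Runs the single-seed model on the given schedule and compares the
#' simulated moisture curve with the experimental one via [percent_error()].
#'
#' @param config A [drying_config()].
#' @param schedule An [air_schedule()].
#' @param exp_curve Experimental drying curve (`time_s`, `mc_wb`).
#' @param duration Simulated time, s; defaults to the last experimental
#'   timestamp.
#' @param out_dt Output cadence of the model curve, s.
#' @param exclude_times Passed to [percent_error()].
#' @return A list with elements `comparison` (a `pe_result`) and
#'   `model_curve` (the simulated `drying_curve`).
#' @export
evaluate_scenario <- function(config, schedule, exp_curve, duration = NULL,
                              out_dt = 600, exclude_times = NULL) {
  exp_curve <- tibble::as_tibble(exp_curve)
  if (is.null(duration)) duration <- max(exp_curve$time_s)
  model_curve <- run_drying(config, schedule, duration = duration,
                            out_dt = out_dt)
  list(comparison = percent_error(exp_curve, model_curve, exclude_times),
       model_curve = model_curve)
}
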