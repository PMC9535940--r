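#' Flow-event generator parameters
#'
#' The wild-type phospho-vs-expression model is piecewise log-linear:
#' below an expression threshold (the 80th percentile of the transfected
#' expression distribution) phospho scales linearly with expression
#' (`phospho = base_scale * expression`); above it, the log-log slope is
#' `slope_hi` (2 by default), emulating the super-linear ("exponential")
#' ligand-independent activation of wild-type receptor at high expression
#' densities. Multiplicative log-normal noise and an additive background
#' floor (the signal of nontransfected cells) complete the model. An
#' activating variant multiplies the specific signal by its activity at all
#' expression levels.
#'
#' @param expr_meanlog,expr_sdlog Log-normal expression distribution of
#'   transfected cells (a.u.).
#' @param base_scale Specific phospho signal per unit expression for wild
#'   type in the linear regime.
#' @param knee_quantile Expression quantile (of the configured expression
#'   distribution) defining the default knee.
#' @param knee Absolute expression level (a.u.) at which the slope changes;
#'   defaults to the `knee_quantile` of the configured expression
#'   distribution. The knee is a property of the receptor density, so it
#'   stays put when the expression distribution is shifted.
#' @param slope_hi Log-log slope above the knee.
#' @param noise_sdlog SD of multiplicative log-normal noise on the specific
#'   signal.
#' @param bg_meanlog,bg_sdlog Background (nontransfected) phospho signal.
#' @param bg_expr_meanlog,bg_expr_sdlog Background expression
#'   (autofluorescence) of nontransfected cells.
#' @return A list of class `flow_sim_params`.
#' @export
flow_sim_params <- function(expr_meanlog = log(1000), expr_sdlog = 1,
                            base_scale = 0.2, knee_quantile = 0.8,
                            knee = NULL,
                            slope_hi = 2, noise_sdlog = 0.35,
                            bg_meanlog = log(5), bg_sdlog = 0.3,
                            bg_expr_meanlog = log(30), bg_expr_sdlog = 0.5) {
  stopifnot(expr_sdlog > 0, base_scale > 0, knee_quantile > 0,
            knee_quantile < 1, slope_hi >= 1, noise_sdlog >= 0)
  if (is.null(knee)) knee <- qlnorm(knee_quantile, expr_meanlog, expr_sdlog)
  stopifnot(knee > 0)
  structure(as.list(environment()), class = "flow_sim_params")
}

#' Simulate two-channel flow-cytometry events
#'
#' Draws per-cell (expression, phospho) signal pairs from the model described
#' in [flow_sim_params()]. With `transfected = FALSE` both channels are
#' background only (the nontransfected population used for background
#' subtraction).
#'
#' @param activity Relative ligand-independent activity (wild type = 1).
#' @param n_events Number of cells (> 0).
#' @param seed Optional integer seed.
#' @param transfected If `FALSE`, generate the background-only population and
#'   ignore `activity`.
#' @param population Label stored per event.
#' @param params A [flow_sim_params()].
#' @param expression Optional vector of pre-drawn expression signals (length
#'   `n_events`), for matched-expression comparisons.
#' @return A data.frame of class `flow_event_set` with columns `expression`,
#'   `phospho`, `population`.
#' @export
simulate_flow_events <- function(activity = 1.0, n_events, seed = NULL,
                                 transfected = TRUE, population = NULL,
                                 params = flow_sim_params(),
                                 expression = NULL) {
  if (length(n_events) != 1L || n_events <= 0) {
    stop("n_events must be a positive integer")
  }
  stopifnot(activity >= 0, inherits(params, "flow_sim_params"))
  n_events <- as.integer(n_events)
  if (!is.null(seed)) set.seed(seed)

  if (!transfected) {
    out <- data.frame(
      expression = rlnorm(n_events, params$bg_expr_meanlog,
                          params$bg_expr_sdlog),
      phospho = rlnorm(n_events, params$bg_meanlog, params$bg_sdlog),
      population = if (is.null(population)) "nontransfected" else population,
      stringsAsFactors = FALSE
    )
    class(out) <- c("flow_event_set", "data.frame")
    return(out)
  }

  e <- if (is.null(expression)) {
    rlnorm(n_events, params$expr_meanlog, params$expr_sdlog)
  } else {
    stopifnot(length(expression) == n_events, all(expression > 0))
    expression
  }
  knee <- params$knee
  base <- ifelse(e <= knee,
                 params$base_scale * e,
                 params$base_scale * knee * (e / knee)^params$slope_hi)
  signal <- activity * base * rlnorm(n_events, 0, params$noise_sdlog)
  bg <- rlnorm(n_events, params$bg_meanlog, params$bg_sdlog)
  out <- data.frame(
    expression = e,
    phospho = signal + bg,
    population = if (is.null(population)) sprintf("activity_%g", activity)
                 else population,
    stringsAsFactors = FALSE
  )
  class(out) <- c("flow_event_set", "data.frame")
  out
}

#' Read / write flow event sets as CSV
#'
#' Columns `expression`, `phospho`, `population`. Native cytometer formats
#' are out of scope; convert FCS exports to this CSV layout upstream.
#'
#' @param events A `flow_event_set`.
#' @param path File path.
#' @return `read_flow_events` returns a `flow_event_set`;
#'   `write_flow_events` returns `path` invisibly.
#' @export
write_flow_events <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flow_events
#' @export
read_flow_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("expression", "phospho") %in% names(df)))
  if (is.null(df$population)) df$population <- "unlabelled"
  class(df) <- c("flow_event_set", "data.frame")
  df
}
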