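#' Jarzynski free-energy estimate
#'
#' `dG = -kT * log( mean( exp(-W_f / kT) ) )` over the forward work samples,
#' evaluated with an overflow-safe log-sum-exp. By Jensen's inequality the
#' estimate never exceeds the mean forward work, with equality only for
#' zero-variance work.
#'
#' @param samples A [work_sample_set()].
#' @return dG in kJ/mol.
#' @export
jarzynski_estimate <- function(samples) {
  stopifnot(inherits(samples, "work_sample_set"))
  w <- samples$forward
  kT <- samples$kT
  x <- -w / kT
  m <- max(x)
  -kT * (m + log(mean(exp(x - m))))
}

#' Crooks-Gaussian intersection free-energy estimate
#'
#' Fits Gaussians by sample moments to the forward work and to the negated
#' reverse work, and returns the abscissa where the two densities cross.
#' With equal variances this is the closed form `(mean(W_f) +
#' mean(-W_r)) / 2`; with unequal variances the quadratic root lying between
#' the two means is chosen (the physically meaningful crossing), and both
#' roots are reported in the `roots` attribute. Sign convention: `reverse`
#' holds the work of the reverse transformation; it is negated internally.
#'
#' @param samples A [work_sample_set()] with at least 2 samples per
#'   direction.
#' @param var_tol Relative variance difference below which the equal-variance
#'   closed form is used.
#' @return dG in kJ/mol, with attribute `roots` when the quadratic was
#'   solved.
#' @export
crooks_gaussian_intersection <- function(samples, var_tol = 1e-9) {
  stopifnot(inherits(samples, "work_sample_set"))
  wf <- samples$forward
  wr <- -samples$reverse
  if (length(wf) < 2L || length(wr) < 2L) {
    stop("Crooks-Gaussian intersection needs >= 2 samples per direction")
  }
  m1 <- mean(wf); m2 <- mean(wr)
  v1 <- mean((wf - m1)^2); v2 <- mean((wr - m2)^2)
  if (v1 <= 0 && v2 <= 0) return((m1 + m2) / 2)
  if (abs(v1 - v2) <= var_tol * max(v1, v2)) {
    return((m1 + m2) / 2)
  }
  # log N1(x) = log N2(x): quadratic a x^2 + b x + c = 0
  a <- 1 / v2 - 1 / v1
  b <- 2 * (m1 / v1 - m2 / v2)
  c <- m2^2 / v2 - m1^2 / v1 + log(v2 / v1)
  disc <- b^2 - 4 * a * c
  if (disc < 0) stop("Gaussian densities do not cross on the real line")
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  lo <- min(m1, m2); hi <- max(m1, m2)
  between <- roots >= lo & roots <= hi
  if (!any(between)) {
    stop(sprintf(
      "no crossing between the fitted means (%.4g, %.4g); roots: %.4g, %.4g",
      m1, m2, roots[1L], roots[2L]))
  }
  out <- roots[between][1L]
  attr(out, "roots") <- roots
  out
}

CYCLE_PROCESSES <- list(
  ins       = c(from = "water",   to = "membrane"),
  `N-dimer` = c(from = "membrane", to = "N-dimer"),
  `C-dimer` = c(from = "membrane", to = "C-dimer"),
  pose      = c(from = "N-dimer", to = "C-dimer")
)

#' Free-energy legs
#'
#' A leg is one edge of the thermodynamic cycle: a physical process
#' (`ins` = insertion from water into the bilayer, `N-dimer` / `C-dimer` =
#' dimerization on the N- or C-terminal motif from the inserted monomer,
#' `pose` = pose change from N- to C-dimer) within one variant state (`wt`
#' or `mutant`), or an alchemical wt-to-mutant transformation within one
#' environment (`state` then names the environment, e.g. `water`,
#' `membrane`, `N-dimer`, `C-dimer`).
#'
#' @param process One of `ins`, `N-dimer`, `C-dimer`, `pose`, `alchemical`.
#' @param state `wt` / `mutant` for physical legs; the environment for
#'   alchemical legs.
#' @param value dG in kJ/mol.
#' @param uncertainty Non-negative, kJ/mol (default 0; none are published
#'   for the printed values).
#' @return A one-row data.frame; rows can be `rbind`-ed into a leg table.
#' @export
free_energy_leg <- function(process, state, value, uncertainty = 0) {
  stopifnot(process %in% c(names(CYCLE_PROCESSES), "alchemical"),
            uncertainty >= 0)
  data.frame(process = process, state = state, value = value,
             uncertainty = uncertainty, stringsAsFactors = FALSE)
}

leg_nodes <- function(legs) {
  lapply(seq_len(nrow(legs)), function(i) {
    p <- legs$process[i]; s <- legs$state[i]
    if (p == "alchemical") {
      c(from = paste0(s, ".wt"), to = paste0(s, ".mutant"))
    } else {
      ends <- CYCLE_PROCESSES[[p]]
      c(from = paste0(ends["from"], ".", s), to = paste0(ends["to"], ".", s))
    }
  })
}

#' Assemble the thermodynamic cycle
#'
#' Computes the mutation-induced free-energy difference of each process,
#' `ddG^X = dG^X_mutant - dG^X_wt`, either directly from wt/mutant legs or
#' equivalently from the alchemical legs spanning the process
#' (`ddG^X = dG^alch_end - dG^alch_start`); the pose-change difference
#' follows as `ddG^pose = ddG^C-dimer - ddG^N-dimer` when no explicit pose
#' legs exist. Every closed loop of the leg graph is reported as a signed-sum
#' residual (zero for any consistent state-energy assignment); uncertainties
#' propagate in quadrature.
#'
#' @param legs Data.frame of [free_energy_leg()] rows.
#' @return A list of class `thermodynamic_cycle`: `ddG` (data.frame
#'   `process`, `value`, `uncertainty`), `closure` (data.frame of loop
#'   residuals, zero rows if the leg graph has no cycles), `legs`.
#' @export
assemble_cycle <- function(legs) {
  legs <- as.data.frame(legs)
  stopifnot(all(c("process", "state", "value") %in% names(legs)))
  if (is.null(legs$uncertainty)) legs$uncertainty <- 0
  dup <- duplicated(legs[c("process", "state")])
  if (any(dup)) stop("duplicate leg(s): ",
                     paste(legs$process[dup], legs$state[dup], collapse = ", "))

  ddg_one <- function(proc) {
    wt <- legs$value[legs$process == proc & legs$state == "wt"]
    mut <- legs$value[legs$process == proc & legs$state == "mutant"]
    u_wt <- legs$uncertainty[legs$process == proc & legs$state == "wt"]
    u_mut <- legs$uncertainty[legs$process == proc & legs$state == "mutant"]
    if (length(wt) == 1L && length(mut) == 1L) {
      return(c(mut - wt, sqrt(u_mut^2 + u_wt^2)))
    }
    ends <- CYCLE_PROCESSES[[proc]]
    a0 <- legs$process == "alchemical" & legs$state == ends["from"]
    a1 <- legs$process == "alchemical" & legs$state == ends["to"]
    if (any(a0) && any(a1)) {
      return(c(legs$value[a1] - legs$value[a0],
               sqrt(legs$uncertainty[a1]^2 + legs$uncertainty[a0]^2)))
    }
    NULL
  }

  ddg <- list()
  for (proc in names(CYCLE_PROCESSES)) {
    v <- ddg_one(proc)
    if (!is.null(v)) ddg[[proc]] <- v
  }
  if (is.null(ddg[["pose"]])) {
    if (is.null(ddg[["N-dimer"]]) || is.null(ddg[["C-dimer"]])) {
      missing <- setdiff(c("N-dimer", "C-dimer"), names(ddg))
      stop("cannot derive ddG^pose: missing leg(s) for ",
           paste(missing, collapse = ", "))
    }
    ddg[["pose"]] <- c(ddg[["C-dimer"]][1L] - ddg[["N-dimer"]][1L],
                       sqrt(ddg[["C-dimer"]][2L]^2 + ddg[["N-dimer"]][2L]^2))
  }
  ddg_df <- data.frame(
    process = names(ddg),
    value = vapply(ddg, `[`, numeric(1L), 1L),
    uncertainty = vapply(ddg, `[`, numeric(1L), 2L),
    row.names = NULL, stringsAsFactors = FALSE
  )

  # Closure residuals: spanning-forest potentials; each non-tree leg closes
  # one independent loop whose signed sum is value - (pot[to] - pot[from]).
  nodes <- leg_nodes(legs)
  all_nodes <- unique(unlist(nodes))
  pot <- setNames(rep(NA_real_, length(all_nodes)), all_nodes)
  in_tree <- rep(FALSE, nrow(legs))
  changed <- TRUE
  for (root in all_nodes) if (is.na(pot[root])) {
    pot[root] <- 0
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (i in seq_len(nrow(legs))) {
        from <- nodes[[i]]["from"]; to <- nodes[[i]]["to"]
        if (!is.na(pot[from]) && is.na(pot[to])) {
          pot[to] <- pot[from] + legs$value[i]
          in_tree[i] <- TRUE; changed <- TRUE
        } else if (is.na(pot[from]) && !is.na(pot[to])) {
          pot[from] <- pot[to] - legs$value[i]
          in_tree[i] <- TRUE; changed <- TRUE
        }
      }
    }
  }
  chords <- which(!in_tree)
  closure <- data.frame(
    loop_through = vapply(chords, function(i)
      paste(legs$process[i], legs$state[i]), character(1L)),
    residual = vapply(chords, function(i) {
      legs$value[i] - (pot[nodes[[i]]["to"]] - pot[nodes[[i]]["from"]])
    }, numeric(1L)),
    stringsAsFactors = FALSE
  )

  structure(list(ddG = ddg_df, closure = closure, legs = legs),
            class = "thermodynamic_cycle")
}

#' @export
print.thermodynamic_cycle <- function(x, ...) {
  cat("<thermodynamic_cycle>\n")
  for (i in seq_len(nrow(x$ddG))) {
    cat(sprintf("  ddG^%-8s = %8.1f kJ/mol", x$ddG$process[i],
                x$ddG$value[i]))
    if (x$ddG$uncertainty[i] > 0) {
      cat(sprintf(" +/- %.1f", x$ddG$uncertainty[i]))
    }
    cat("\n")
  }
  if (nrow(x$closure) > 0L) {
    cat(sprintf("  max |closure residual| = %.3g kJ/mol\n",
                max(abs(x$closure$residual))))
  }
  invisible(x)
}

#' Read / write free-energy legs as TSV
#'
#' Columns `process`, `state`, `value`, `uncertainty`.
#'
#' @param legs A leg table.
#' @param path File path.
#' @return `read_free_energy_legs` returns the leg data.frame;
#'   `write_free_energy_legs` returns `path` invisibly.
#' @export
read_free_energy_legs <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("process", "state", "value") %in% names(df)))
  if (is.null(df$uncertainty)) df$uncertainty <- 0
  df
}

#' @rdname read_free_energy_legs
#' @export
write_free_energy_legs <- function(legs, path) {
  write.table(as.data.frame(legs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
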