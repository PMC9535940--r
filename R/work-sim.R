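#' Thermal energy at a given temperature
#'
#' `kT` in kJ/mol; the default 310 K gives 2.577 kJ/mol, the temperature at
#' which the dimerization simulations were thermostatted.
#'
#' @param temperature Kelvin.
#' @return kT in kJ/mol.
#' @export
boltzmann_kT <- function(temperature = 310) {
  stopifnot(temperature > 0)
  0.0083144626 * temperature
}

#' Nonequilibrium work sample sets
#'
#' Container for forward and reverse work values (kJ/mol) of a switching
#' process, the input of the Jarzynski and Crooks-Gaussian estimators.
#' Sign convention: `reverse` stores the work of the *reverse*
#' transformation; the Crooks comparison negates it internally, i.e. the
#' fitted reverse density is that of `-W_r`.
#'
#' @param forward Numeric vector, `n >= 1`.
#' @param reverse Numeric vector (may be empty; the Jarzynski estimator needs
#'   forward work only).
#' @param kT Thermal energy in kJ/mol (> 0).
#' @return A list of class `work_sample_set`.
#' @export
work_sample_set <- function(forward, reverse = numeric(), kT = boltzmann_kT()) {
  stopifnot(is.numeric(forward), length(forward) >= 1L,
            is.numeric(reverse), is.numeric(kT), kT > 0)
  structure(list(forward = as.numeric(forward),
                 reverse = as.numeric(reverse), kT = kT),
            class = "work_sample_set")
}

#' @export
print.work_sample_set <- function(x, ...) {
  cat(sprintf(
    "<work_sample_set> n_f = %d, n_r = %d, kT = %.4g kJ/mol\n",
    length(x$forward), length(x$reverse), x$kT))
  invisible(x)
}

#' Simulate Crooks-consistent Gaussian work samples
#'
#' Generates forward work `~ Normal(dG_true + sigma^2/(2 kT), sigma^2)` and
#' reverse-process work `~ Normal(-dG_true + sigma^2/(2 kT), sigma^2)`. With
#' these means the two distributions satisfy the Crooks fluctuation relation
#' exactly, so both estimators should recover `dG_true` in the large-sample
#' limit; the set serves as ground truth for estimator-recovery tests.
#'
#' @param dG_true True free-energy difference (kJ/mol).
#' @param sigma Work standard deviation (kJ/mol, >= 0).
#' @param n Samples per direction (>= 1).
#' @param kT Thermal energy (kJ/mol, > 0).
#' @param seed Optional integer seed.
#' @return A [work_sample_set()].
#' @export
simulate_work_samples <- function(dG_true, sigma, n, kT = boltzmann_kT(),
                                  seed = NULL) {
  stopifnot(sigma >= 0, n >= 1)
  if (kT <= 0) stop("kT must be positive")
  if (!is.null(seed)) set.seed(seed)
  shift <- sigma^2 / (2 * kT)
  work_sample_set(
    forward = rnorm(n, dG_true + shift, sigma),
    reverse = rnorm(n, -dG_true + shift, sigma),
    kT = kT
  )
}

#' Read / write work samples as TSV
#'
#' Columns `direction` (`forward` / `reverse`) and `work_kJ_mol`; `kT` is
#' kept in a `# kT=<value>` header line.
#'
#' @param samples A [work_sample_set()].
#' @param path File path.
#' @param kT Thermal energy used if the file has no `# kT=` header.
#' @return `read_work_samples` returns a [work_sample_set()];
#'   `write_work_samples` returns `path` invisibly.
#' @export
write_work_samples <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kT=%.10g", samples$kT), con)
  df <- data.frame(
    direction = rep(c("forward", "reverse"),
                    c(length(samples$forward), length(samples$reverse))),
    work_kJ_mol = c(samples$forward, samples$reverse)
  )
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_work_samples
#' @export
read_work_samples <- function(path, kT = boltzmann_kT()) {
  first <- readLines(path, n = 1L)
  if (grepl("^# kT=", first)) kT <- as.numeric(sub("^# kT=", "", first))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  work_sample_set(df$work_kJ_mol[df$direction == "forward"],
                  df$work_kJ_mol[df$direction == "reverse"], kT = kT)
}
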