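#' Individual increase in inbreeding from a molecular coefficient
#'
#' Converts a per-individual inbreeding coefficient into a standardised
#' per-generation rate relative to the reference generation:
#' \deqn{\Delta F = 1 - (1 - F)^{1/t}}
#' where t is the number of generations elapsed since the reference
#' generation (for an animal of selection generation g with the
#' reference population at generation 1, t = g - 1). Negative F gives a
#' base above 1 and hence a negative rate, which is allowed; t <= 0
#' yields \code{NA} (the reference generation itself has no rate).
#' Values of F at or above 1 are clamped to 1 - 1e-12 with a warning.
#'
#' @param f Numeric vector of inbreeding coefficients (e.g. the
#'   adjusted \eqn{F_{NEJ0}}, \eqn{F_{L\&H0}}, \eqn{F_{ROH0}}, or
#'   \eqn{F_{VR1}}, \eqn{F_{VR2}}, \eqn{F_{YAN}}).
#' @param t Generations since the reference generation (vector recycled
#'   against \code{f}).
#' @return Numeric vector of \eqn{\Delta F}.
#' @export
deltaFMolecular <- function(f, t) {
    n <- max(length(f), length(t))
    f <- rep_len(f, n)
    t <- rep_len(t, n)
    hi <- !is.na(f) & f >= 1
    if (any(hi)) {
        warning(sum(hi), " coefficient(s) at or above 1 clamped")
        f[hi] <- 1 - 1e-12
    }
    out <- ifelse(!is.na(t) & t >= 1, 1 - (1 - f)^(1 / t), NA_real_)
    names(out) <- names(f)
    out
}

#' Per-generation mean rates and effective population size
#'
#' Groups per-individual increases in inbreeding by generation and
#' estimator, averages them, and converts each mean rate into
#' \eqn{N_e = 1/(2\overline{\Delta F})}. Also reports, per estimator,
#' the mean and standard deviation of Ne across generations (negative
#' Ne included, undefined generations excluded).
#'
#' @param rates A \code{data.frame} with columns \code{generation},
#'   \code{estimator}, \code{delta_f} (per animal; \code{NA} allowed).
#' @return A list with \code{byGeneration} (columns \code{generation},
#'   \code{estimator}, \code{mean_delta_f}, \code{ne}, \code{n}) and
#'   \code{summary} (columns \code{estimator}, \code{mean_ne},
#'   \code{sd_ne}).
#' @export
nePerGeneration <- function(rates) {
    stopifnot(all(c("generation", "estimator", "delta_f") %in%
                  names(rates)))
    key <- interaction(rates$generation, rates$estimator, drop = TRUE)
    rows <- lapply(split(rates, key), function(d) {
        ok <- !is.na(d$delta_f)
        mdf <- if (any(ok)) mean(d$delta_f[ok]) else NA_real_
        data.frame(generation = d$generation[1L],
                   estimator = d$estimator[1L],
                   mean_delta_f = mdf,
                   ne = if (!is.na(mdf) && mdf != 0) 1 / (2 * mdf)
                        else NA_real_,
                   n = sum(ok), stringsAsFactors = FALSE)
    })
    byGen <- do.call(rbind, rows)
    byGen <- byGen[order(byGen$estimator, byGen$generation), ]
    rownames(byGen) <- NULL
    summ <- do.call(rbind, lapply(split(byGen, byGen$estimator),
        function(d) data.frame(
            estimator = d$estimator[1L],
            mean_ne = mean(d$ne, na.rm = TRUE),
            sd_ne = stats::sd(d$ne, na.rm = TRUE),
            stringsAsFactors = FALSE)))
    rownames(summ) <- NULL
    list(byGeneration = byGen, summary = summ)
}

#' Effective population size from expected homozygosity
#'
#' Between consecutive generations of an expected-homozygosity series,
#' \deqn{\Delta F_{EXP,t} = (F_{EXP,t} - F_{EXP,t-1}) /
#'       (1 - F_{EXP,t-1})}
#' and \eqn{N_e = 1/(2\Delta F_{EXP})}. The first generation of each
#' group has no predecessor and a zero rate leaves Ne undefined; both
#' give \code{NA}.
#'
#' @param series Output of [fExpSeries()].
#' @return The series with added columns \code{delta_f_exp} and
#'   \code{ne}.
#' @export
neExpected <- function(series) {
    stopifnot(all(c("group", "generation", "f_exp") %in% names(series)))
    out <- do.call(rbind, lapply(split(series, series$group), function(d) {
        d <- d[order(d$generation), ]
        prev <- c(NA_real_, d$f_exp[-nrow(d)])
        d$delta_f_exp <- (d$f_exp - prev) / (1 - prev)
        d$ne <- ifelse(is.na(d$delta_f_exp) | d$delta_f_exp == 0,
                       NA_real_, 1 / (2 * d$delta_f_exp))
        d
    }))
    rownames(out) <- NULL
    out
}

#' Generations back to the founder population
#'
#' Convenience wrapper around [estimateT()]: the rate may be given
#' directly or derived from an effective population size as
#' \eqn{\Delta F = 1/(2 N_e)} (e.g. the sex-ratio Ne of the base
#' breeding design).
#'
#' @param fRefMean Mean inbreeding of the reference population (e.g.
#'   mean \eqn{F_{NEJ}}, \eqn{F_{ROH}} or \eqn{F_{PED}} of the first
#'   selection generation).
#' @param deltaF Per-generation rate; exactly one of \code{deltaF} and
#'   \code{ne} must be given.
#' @param ne Effective population size from which to derive the rate.
#' @return Estimated number of generations.
#' @examples
#' founderDistance(0.61, ne = neSexRatio(32, 64))
#' @export
founderDistance <- function(fRefMean, deltaF = NULL, ne = NULL) {
    if (is.null(deltaF) == is.null(ne))
        stop("give exactly one of deltaF or ne")
    if (!is.null(ne)) deltaF <- 1 / (2 * ne)
    estimateT(fRefMean, deltaF)
}
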