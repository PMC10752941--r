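#' Default generation groupings for correlation reports
#'
#' Initial (1-4), intermediate (16-19) and most recent (23-26)
#' selection generations, alongside the full span.
#'
#' @param nGenerations Last selection generation (default 26).
#' @return Named list of generation vectors.
#' @export
generationGroups <- function(nGenerations = 26) {
    g <- list(all = seq_len(nGenerations),
              initial = 1:4,
              intermediate = 16:19,
              recent = (nGenerations - 3):nGenerations)
    lapply(g, function(x) x[x >= 1 & x <= nGenerations])
}

#' Pearson correlations among estimators, overall and by generation group
#'
#' Computes pairwise-complete Pearson correlation matrices between the
#' value columns of a per-animal table (inbreeding coefficients or
#' increases in inbreeding), for the whole table and within each
#' generation group. Pairwise-complete deletion is used because some
#' rates are undefined in the first generation. Cells with fewer than
#' \code{minPairs} complete pairs, or with a zero-variance column, are
#' \code{NA}.
#'
#' @param values A \code{data.frame} with a \code{generation} column
#'   and one numeric column per estimator.
#' @param groups Named list of generation vectors; default
#'   [generationGroups()].
#' @param minPairs Minimum complete pairs per cell (default 3).
#' @return A named list of correlation matrices, one per group, each
#'   with an \code{"n_pairs"} attribute holding the pair counts.
#' @export
correlateInbreeding <- function(values,
                                groups = generationGroups(
                                    max(values$generation, na.rm = TRUE)),
                                minPairs = 3) {
    stopifnot("generation" %in% names(values))
    num <- vapply(values, is.numeric, logical(1))
    num["generation"] <- FALSE
    cols <- names(values)[num]
    if (length(cols) < 2)
        stop("need at least two numeric estimator columns")
    out <- list()
    for (gname in names(groups)) {
        sel <- !is.na(values$generation) &
            values$generation %in% groups[[gname]]
        if (!any(sel)) next   # group outside the observed generations
        x <- as.matrix(values[sel, cols, drop = FALSE])
        npair <- crossprod(!is.na(x))
        suppressWarnings(
            r <- stats::cor(x, use = "pairwise.complete.obs"))
        r[npair < minPairs] <- NA_real_
        d <- diag(r)
        d[diag(npair) >= minPairs] <- 1
        diag(r) <- d
        attr(r, "n_pairs") <- npair
        out[[gname]] <- r
    }
    out
}
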