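#' Per-regulator involvement rates and ratio
#'
#' For every regulator appearing in at least one TRA alteration, computes
#' the involvement rate within each timepoint class — the percentage of
#' that class's alterations whose mutated base overlaps the regulator's
#' clusters — and the involvement ratio (additional rate over common
#' rate). Rates and the ratio are computed on unrounded values; rounding
#' happens only at serialization. A regulator involved in additional but
#' in no common alterations has an undefined ratio and is flagged
#' \code{additional_exclusive} (never a numeric sentinel); the converse is
#' \code{common_exclusive} (ratio 0).
#'
#' Rows are ordered the way the involvement figure is drawn: additional-
#' exclusive regulators first (undefined ratio ordered as +Inf), then by
#' ratio descending, ties broken by additional rate descending, then by
#' regulator name ascending.
#'
#' @param commonAlts,additionalAlts \linkS4class{TRAAlterations} (or any
#'   object with an \code{involved} CharacterList column) for the common
#'   and additional classes.
#' @return A data.frame with columns \code{regulator},
#'   \code{n_common_involved}, \code{N_common}, \code{common_rate},
#'   \code{n_additional_involved}, \code{N_additional},
#'   \code{additional_rate}, \code{ratio} (NA when undefined),
#'   \code{exclusivity}.
#' @export
involvementTable <- function(commonAlts, additionalAlts) {
    nC <- length(commonAlts)
    nA <- length(additionalAlts)
    if (nC == 0L && nA == 0L) {
        warning("no alterations in either class; empty involvement table")
        return(data.frame(regulator = character(0),
                          n_common_involved = integer(0),
                          N_common = integer(0), common_rate = numeric(0),
                          n_additional_involved = integer(0),
                          N_additional = integer(0),
                          additional_rate = numeric(0), ratio = numeric(0),
                          exclusivity = character(0)))
    }
    countInvolved <- function(alts) {
        inv <- mcols(alts)$involved
        table(unlist(lapply(inv, unique)))
    }
    tc <- countInvolved(commonAlts)
    ta <- countInvolved(additionalAlts)
    regs <- sort(union(names(tc), names(ta)))
    nCi <- as.integer(ifelse(regs %in% names(tc), tc[regs], 0L))
    nAi <- as.integer(ifelse(regs %in% names(ta), ta[regs], 0L))
    commonRate <- if (nC > 0L) 100 * nCi / nC else rep(0, length(regs))
    additionalRate <- if (nA > 0L) 100 * nAi / nA else rep(0, length(regs))
    ratio <- ifelse(commonRate > 0, additionalRate / commonRate, NA_real_)
    exclusivity <- ifelse(commonRate == 0 & additionalRate > 0,
                          "additional_exclusive",
                   ifelse(additionalRate == 0 & commonRate > 0,
                          "common_exclusive", "none"))
    ratio[exclusivity == "common_exclusive"] <- 0
    df <- data.frame(regulator = regs,
                     n_common_involved = nCi, N_common = nC,
                     common_rate = commonRate,
                     n_additional_involved = nAi, N_additional = nA,
                     additional_rate = additionalRate,
                     ratio = ratio, exclusivity = exclusivity)
    sortKey <- ifelse(is.na(df$ratio), Inf, df$ratio)
    df <- df[order(-sortKey, -df$additional_rate, df$regulator), ]
    rownames(df) <- NULL
    df
}

#' Flag regulators skewed toward additional alterations
#'
#' Flags regulators whose involvement ratio meets the threshold (default
#' 2, "more than two folds") or that are exclusively engaged in
#' additional alterations. Exclusive regulators with a low additional
#' rate get a low-frequency caveat (they are flagged "albeit less
#' frequently").
#'
#' @param table an involvement table from [involvementTable()].
#' @param ratioThreshold inclusive ratio threshold (default 2).
#' @param lowFreqBelow additional-rate percentage under which an
#'   exclusive regulator is marked low-frequency (default 5).
#' @return The flagged subset of \code{table} with logical columns
#'   \code{skewed} and \code{low_frequency} added.
#' @export
skewReport <- function(table, ratioThreshold = 2, lowFreqBelow = 5) {
    excl <- table$exclusivity == "additional_exclusive"
    flag <- excl | (!is.na(table$ratio) & table$ratio >= ratioThreshold)
    out <- table[flag, , drop = FALSE]
    out$skewed <- TRUE
    out$low_frequency <- out$exclusivity == "additional_exclusive" &
        out$additional_rate < lowFreqBelow
    rownames(out) <- NULL
    out
}

#' Serialize an involvement table
#'
#' Writes the TSV report; rates and ratio are rounded to one decimal at
#' this point only (internal arithmetic is unrounded), and undefined
#' ratios are written as \code{NA} with the exclusivity column carrying
#' the class.
#'
#' @param table an involvement table from [involvementTable()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeInvolvementTable <- function(table, path) {
    out <- table
    out$common_rate <- round(out$common_rate, 1)
    out$additional_rate <- round(out$additional_rate, 1)
    out$ratio <- round(out$ratio, 2)
    .writeTsv(out, path)
}

#' Plot involvement rates and ratio
#'
#' Draws the dual-axis figure: involvement rates of the two classes as
#' dodged bars and the ratio as a point series, regulators on the x-axis
#' in table (ratio) order. Requires ggplot2.
#'
#' @param table an involvement table from [involvementTable()].
#' @param ratioAxisScale how many rate-percent units one ratio unit
#'   occupies on the secondary axis (default 10).
#' @return A ggplot object.
#' @export
plotInvolvement <- function(table, ratioAxisScale = 10) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("plotInvolvement requires ggplot2")
    df <- table
    df$regulator <- factor(df$regulator, levels = df$regulator)
    long <- rbind(
        data.frame(regulator = df$regulator, class = "common",
                   rate = df$common_rate),
        data.frame(regulator = df$regulator, class = "additional",
                   rate = df$additional_rate))
    p <- ggplot2::ggplot(long,
                         ggplot2::aes(x = .data$regulator, y = .data$rate,
                                      fill = .data$class)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::geom_point(data = df[!is.na(df$ratio), ],
                            ggplot2::aes(y = .data$ratio * ratioAxisScale),
                            inherit.aes = FALSE,
                            mapping = ggplot2::aes(x = .data$regulator,
                                                   y = .data$ratio * ratioAxisScale),
                            colour = "darkgreen") +
        ggplot2::scale_y_continuous(
            name = "involvement rate (%)",
            sec.axis = ggplot2::sec_axis(~ . / ratioAxisScale,
                                         name = "ratio (additional/common)")) +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           vjust = 0.5))
    p
}
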