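#' Parse protein variant notation
#'
#' Accepts compact one-letter tokens ("R123H", "W10*", "L7L", "L7=") and
#' HGVS-p three-letter tokens ("p.Arg123His", "p.Trp10Ter", "p.Leu7=").
#' Substitutions to the wild-type residue are canonicalized to the
#' synonymous code \code{"="}; stop gains are coded \code{"*"}.
#' Coordinates are 1-based protein positions.
#'
#' @param x character vector of variant tokens
#' @return data.frame with columns \code{position} (integer), \code{wt}
#'   and \code{alt} (one-letter codes, \code{alt} may be \code{"*"} or
#'   \code{"="}), one row per token
#' @examples
#' parseVariant(c("R123H", "p.Trp10Ter", "L7L"))
#' @export
parseVariant <- function(x) {
    x <- trimws(as.character(x))
    n <- length(x)
    wt <- alt <- rep(NA_character_, n)
    pos <- rep(NA_integer_, n)

    re_hgvs <- "^p\\.([A-Z][a-z]{2})([0-9]+)((?:[A-Z][a-z]{2})|\\*|=)$"
    re_compact <- "^([A-Z])([0-9]+)([A-Z*=])$"

    is_h <- grepl(re_hgvs, x)
    if (any(is_h)) {
        m <- regmatches(x[is_h], regexec(re_hgvs, x[is_h]))
        wt3 <- vapply(m, `[`, "", 2L)
        alt3 <- vapply(m, `[`, "", 4L)
        pos[is_h] <- as.integer(vapply(m, `[`, "", 3L))
        wt[is_h] <- unname(AA_THREE_TO_ONE[wt3])
        alt[is_h] <- ifelse(alt3 == "=", "=",
                     ifelse(alt3 == "*", "*", unname(AA_THREE_TO_ONE[alt3])))
    }
    is_c <- !is_h & grepl(re_compact, x)
    if (any(is_c)) {
        m <- regmatches(x[is_c], regexec(re_compact, x[is_c]))
        wt[is_c] <- vapply(m, `[`, "", 2L)
        pos[is_c] <- as.integer(vapply(m, `[`, "", 3L))
        alt[is_c] <- vapply(m, `[`, "", 4L)
    }

    ok <- (is_h | is_c) & !is.na(wt) & wt %in% AA_ALPHABET20 &
        !is.na(alt) & (alt %in% c(AA_ALPHABET20, "*", "=")) &
        !is.na(pos) & pos >= 1L
    if (!all(ok))
        stop("malformed variant token(s): ",
             paste(utils::head(x[!ok], 5L), collapse = ", "),
             if (sum(!ok) > 5L) sprintf(" (and %d more)", sum(!ok) - 5L),
             call. = FALSE)
    alt[alt == wt] <- "="   # synonymous canonical form
    data.frame(position = pos, wt = wt, alt = alt,
               stringsAsFactors = FALSE)
}

#' Format variant keys as tokens
#'
#' Inverse of \code{\link{parseVariant}}: renders (position, wt, alt)
#' triples in compact one-letter form ("R123H", "W10*", "L7=") or HGVS-p
#' three-letter form.
#'
#' @param keys data.frame with columns position, wt, alt
#' @param style "compact" or "hgvs"
#' @return character vector of tokens
#' @export
formatVariant <- function(keys, style = c("compact", "hgvs")) {
    style <- match.arg(style)
    if (style == "compact")
        return(paste0(keys$wt, keys$position, keys$alt))
    alt3 <- ifelse(keys$alt == "=", "=",
            ifelse(keys$alt == "*", "Ter", AA_ONE_TO_THREE[keys$alt]))
    paste0("p.", AA_ONE_TO_THREE[keys$wt], keys$position, alt3)
}

#' Classify variants as stop, synonymous or missense
#'
#' @param alt vector of one-letter alternate codes ("*" stop, "=" synonymous)
#' @return character vector in {"stop", "synonymous", "missense"}
#' @export
variantClass <- function(alt) {
    ifelse(alt == "*", "stop", ifelse(alt == "=", "synonymous", "missense"))
}

# compact id used as the join key across tables
variantId <- function(keys) paste0(keys$wt, keys$position, keys$alt)
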