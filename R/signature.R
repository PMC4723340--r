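#' Per-clutch intensity intervals for one gene
#'
#' @param values numeric vector of log2 intensities, one per sample
#' @param clutch clutch assignment (factor level order fixes the digit
#'   order of profile codes)
#' @return matrix with rows `min`, `max` and one column per clutch
#' @export
clutch_ranges <- function(values, clutch) {
  clutch <- as.factor(clutch)
  if (any(table(clutch) < 2))
    stop("every clutch needs >= 2 samples")
  sapply(levels(clutch), function(cl) {
    x <- values[clutch == cl]
    c(min = min(x), max = max(x))
  })
}

#' Detect absolutely distinct mother-specific expression levels
#'
#' Clutch intervals are merged into level groups by transitive overlap,
#' where closed intervals `[a,b]` and `[c,d]` overlap iff `a <= d` and
#' `c <= b` (a shared endpoint counts as overlap, so a distinct level
#' requires a strict gap). If more than one group remains, the gene shows
#' absolutely distinct mother-specific levels: groups are ranked by hull
#' midpoint descending (ties by group minimum, higher first) and encoded
#' as a digit string with one digit per mother, digit = level rank
#' (1 = highest).
#'
#' @param intervals matrix as returned by [clutch_ranges()] (rows `min`,
#'   `max`, one column per clutch, in fixed mother order)
#' @return list of class `clutch_profile`: `n_levels`, `code` (NA when
#'   `n_levels` is 1), `level_groups` (list of clutch-name vectors, highest
#'   level first), `intervals`
#' @export
detect_distinct_levels <- function(intervals) {
  lo <- intervals["min", ]
  hi <- intervals["max", ]
  k <- length(lo)
  ord <- order(lo)
  # sweep in order of interval start; a strict gap starts a new group
  grp <- integer(k)
  g <- 1L
  grp[ord[1]] <- g
  reach <- hi[ord[1]]
  for (i in seq_len(k)[-1]) {
    j <- ord[i]
    if (lo[j] > reach) g <- g + 1L
    grp[j] <- g
    reach <- max(reach, hi[j])
  }
  n_levels <- max(grp)
  groups <- split(colnames(intervals), grp)
  mids <- vapply(groups, function(cl)
    (min(lo[cl]) + max(hi[cl])) / 2, numeric(1))
  mins <- vapply(groups, function(cl) min(lo[cl]), numeric(1))
  rank_ord <- order(-mids, -mins)
  groups <- groups[rank_ord]
  code <- NA_character_
  if (n_levels > 1) {
    digit <- integer(k)
    for (lev in seq_along(groups))
      digit[match(groups[[lev]], colnames(intervals))] <- lev
    code <- paste(digit, collapse = "")
  }
  structure(list(n_levels = n_levels, code = code,
                 level_groups = unname(groups), intervals = intervals),
            class = "clutch_profile")
}

#' Profile every gene of an expression matrix
#'
#' @param gm genes x samples matrix of log2 intensities
#' @param clutch clutch assignment per column
#' @return data.frame per gene: `gene_id`, `n_levels`, `code`
#' @export
profile_genes <- function(gm, clutch) {
  clutch <- as.factor(clutch)
  res <- lapply(seq_len(nrow(gm)), function(i)
    detect_distinct_levels(clutch_ranges(gm[i, ], clutch)))
  data.frame(gene_id = rownames(gm),
             n_levels = vapply(res, `[[`, integer(1), "n_levels"),
             code = vapply(res, `[[`, character(1), "code"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group signature genes into clusters by profile code
#'
#' One cluster per distinct code among genes with more than one level,
#' ordered by size descending (ties by code). `min_size` is a reporting
#' filter (the full clustering is returned with a `reported` flag).
#'
#' @param profiles data.frame from [profile_genes()]
#' @param min_size report threshold on cluster size (default 25)
#' @return data.frame per cluster: `code`, `n_genes`, `genes` (list
#'   column), `inverse_code` (for two-level codes; NA otherwise),
#'   `reported`
#' @export
group_clusters <- function(profiles, min_size = 25) {
  sig <- profiles[!is.na(profiles$code) & profiles$n_levels > 1, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(code = character(0), n_genes = integer(0),
                      inverse_code = character(0), reported = logical(0)))
  by_code <- split(sig$gene_id, sig$code)
  out <- data.frame(code = names(by_code),
                    n_genes = lengths(by_code),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$genes <- unname(by_code)
  out$inverse_code <- vapply(out$code, inverse_code, character(1))
  out <- out[order(-out$n_genes, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out$reported <- out$n_genes >= min_size
  out
}

#' Inverse of a two-level profile code (1 <-> 2)
#' @param code digit string
#' @return the inverse code, or NA for codes with more than two levels
#' @export
inverse_code <- function(code) {
  digits <- strsplit(code, "")[[1]]
  if (any(!digits %in% c("1", "2"))) return(NA_character_)
  paste(chartr("12", "21", digits), collapse = "")
}

#' Inverse-profile pairs present among clusters
#'
#' @param clusters data.frame from [group_clusters()]
#' @return data.frame of unordered pairs (`code`, `inverse_code`) where
#'   both members exist among the clusters; codes with more than two
#'   levels are skipped with a message
#' @export
find_inverse_pairs <- function(clusters) {
  codes <- clusters$code
  two_level <- !is.na(clusters$inverse_code)
  if (any(!two_level))
    message(sum(!two_level), " cluster code(s) with >2 levels skipped")
  pairs <- list()
  seen <- character(0)
  for (code in codes[two_level]) {
    inv <- inverse_code(code)
    if (inv %in% codes && !(code %in% seen)) {
      pairs[[length(pairs) + 1L]] <- c(code, inv)
      seen <- c(seen, code, inv)
    }
  }
  if (!length(pairs))
    return(data.frame(code = character(0), inverse_code = character(0)))
  out <- do.call(rbind, pairs)
  data.frame(code = out[, 1], inverse_code = out[, 2],
             stringsAsFactors = FALSE)
}
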