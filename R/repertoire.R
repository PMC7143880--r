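# Conserved vs strain-specific cluster repertoires between two strains, and
# the RC statistic: RC (%) = 2 * Cab / (A + B) * 100, a Dice-type overlap of
# the two strains' PKS/NRPS cluster sets (A, B cluster counts; Cab conserved
# pairs).

cluster_modules <- function(cl) {
  unlist(lapply(cl$orfs, `[[`, "modules"), recursive = FALSE)
}

# precomputed module signature: class, domain-kind count vector, substrate
module_sig <- function(m) {
  kinds <- module_kinds(m)
  counts <- tabulate(match(kinds, DOMAIN_KINDS), nbins = length(DOMAIN_KINDS))
  list(class = classify_module(m), counts = counts, n = length(kinds),
       substrate = module_substrate(m))
}

cluster_sig <- function(cl) lapply(cluster_modules(cl), module_sig)

# per-module comparison used by the alignment: same class required; domain
# content compared by Dice similarity of the domain-kind multisets, then
# scaled by substrate agreement (1 identical or both absent, 0.5 one-sided,
# 0.25 both called but different)
sig_pair_score <- function(s1, s2) {
  if (s1$class != s2$class) return(0)
  dice <- 2 * sum(pmin(s1$counts, s2$counts)) / (s1$n + s2$n)
  f <- if (is.na(s1$substrate) && is.na(s2$substrate)) 1
       else if (is.na(s1$substrate) || is.na(s2$substrate)) 0.5
       else if (s1$substrate == s2$substrate) 1 else 0.25
  dice * f
}

sig_similarity <- function(sig1, sig2) {
  n1 <- length(sig1); n2 <- length(sig2)
  if (n1 == 0 || n2 == 0) return(0)
  gap <- -0.25
  prev <- gap * (0:n2)
  for (i in seq_len(n1)) {
    cur <- numeric(n2 + 1)
    cur[1] <- gap * i
    for (j in seq_len(n2)) {
      cur[j + 1] <- max(prev[j] + sig_pair_score(sig1[[i]], sig2[[j]]),
                        prev[j + 1] + gap,
                        cur[j] + gap)
    }
    prev <- cur
  }
  max(0, min(1, prev[n2 + 1] / max(n1, n2)))
}

#' Architecture similarity between two gene clusters
#'
#' Zero when the cluster types differ. Otherwise a global (Needleman-Wunsch)
#' alignment of the two ordered module sequences, scoring aligned modules by
#' class identity, Dice similarity of domain content and substrate
#' agreement, with a cost of 0.25 per unaligned module, normalized by the
#' longer module count. Symmetric, in `[0, 1]`, and `1` exactly for
#' identical architectures. A cluster pair differing only in one substrate
#' call out of four modules scores `(3 + 0.25)/4 = 0.8125`.
#'
#' @param c1,c2 `bgc_cluster` objects.
#' @return a similarity score in `[0, 1]`.
#' @export
cluster_similarity <- function(c1, c2) {
  if (c1$ctype != c2$ctype) return(0)
  sig_similarity(cluster_sig(c1), cluster_sig(c2))
}

#' Build or read a conservation map
#'
#' A conservation map is the set of matched (conserved) cluster pairs
#' between two strains: a data frame with columns `cluster_id_A`,
#' `cluster_id_B`, `score`, plus a `source` attribute (`"given"` for an
#' expert call such as a published boldface annotation, `"inferred"` for
#' [infer_conservation()] output). Each cluster id appears at most once.
#'
#' @param pairs data frame with columns `cluster_id_A`, `cluster_id_B` and
#'   optionally `score` (defaults to 1).
#' @param source `"given"` or `"inferred"`.
#' @return a `bgc_conservation_map` (a data frame).
#' @export
conservation_map <- function(pairs, source = c("given", "inferred")) {
  source <- match.arg(source)
  if (is.null(pairs$score)) pairs$score <- rep(1, nrow(pairs))
  pairs <- pairs[, c("cluster_id_A", "cluster_id_B", "score"), drop = FALSE]
  if (anyDuplicated(pairs$cluster_id_A) || anyDuplicated(pairs$cluster_id_B)) {
    bgc_stop("bgcrep_format_error",
             "conservation map must be one-to-one (no repeated cluster id)")
  }
  if (nrow(pairs) && (any(pairs$score < 0) || any(pairs$score > 1))) {
    bgc_stop("bgcrep_format_error", "conservation scores must lie in [0, 1]")
  }
  pairs <- pairs[order(pairs$cluster_id_A), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, source = source,
            class = c("bgc_conservation_map", "data.frame"))
}

#' @rdname conservation_map
#' @param path TSV file with columns `cluster_id_A`, `cluster_id_B`,
#'   optional `score`; `#` comments allowed.
#' @export
read_conservation_map <- function(path, source = "given") {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  conservation_map(df, source = source)
}

# exact maximum-weight bipartite matching on the thresholded score matrix.
# Eligible edges are decomposed into connected components; each component is
# solved by dynamic programming over (row index, used-column bitmask).
# Ties are broken deterministically: rows are processed in lexicographic
# cluster-id order and, at equal total score, matching the current row to its
# lexicographically smallest optimal partner beats leaving it unmatched.
max_weight_matching <- function(score, row_ids, col_ids) {
  n1 <- length(row_ids); n2 <- length(col_ids)
  eligible <- score > 0
  if (!any(eligible)) {
    return(data.frame(cluster_id_A = character(0),
                      cluster_id_B = character(0), score = numeric(0)))
  }
  # connected components of the bipartite eligibility graph
  comp_row <- rep(NA_integer_, n1); comp_col <- rep(NA_integer_, n2)
  ncomp <- 0L
  for (r in seq_len(n1)) {
    if (!is.na(comp_row[r]) || !any(eligible[r, ])) next
    ncomp <- ncomp + 1L
    qr <- r
    while (length(qr)) {
      comp_row[qr] <- ncomp
      qc <- setdiff(which(apply(eligible[qr, , drop = FALSE], 2, any)),
                    which(!is.na(comp_col)))
      comp_col[qc] <- ncomp
      qr <- setdiff(which(apply(eligible[, qc, drop = FALSE], 1, any)),
                    which(!is.na(comp_row)))
    }
  }
  out <- list()
  eps <- 1e-9
  for (cc in seq_len(ncomp)) {
    rows <- which(comp_row == cc); cols <- which(comp_col == cc)
    rows <- rows[order(row_ids[rows])]
    cols <- cols[order(col_ids[cols])]
    if (length(cols) > 22) {
      bgc_stop("bgcrep_error",
               "matching component too large for exact assignment")
    }
    memo <- new.env(parent = emptyenv())
    best <- function(i, mask) {
      if (i > length(rows)) return(0)
      key <- paste0(i, ".", mask)
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
      v <- best(i + 1, mask)  # leave row i unmatched
      for (jj in seq_along(cols)) {
        bit <- bitwShiftL(1L, jj - 1L)
        if (bitwAnd(mask, bit) == 0L && eligible[rows[i], cols[jj]]) {
          v <- max(v, score[rows[i], cols[jj]] + best(i + 1, bitwOr(mask, bit)))
        }
      }
      memo[[key]] <- v
      v
    }
    total <- best(1, 0L)
    # reconstruct, preferring a match (lex-smallest partner) at ties
    mask <- 0L
    for (i in seq_along(rows)) {
      target <- best(i, mask)
      matched <- FALSE
      for (jj in seq_along(cols)) {
        bit <- bitwShiftL(1L, jj - 1L)
        if (bitwAnd(mask, bit) == 0L && eligible[rows[i], cols[jj]] &&
            abs(score[rows[i], cols[jj]] + best(i + 1, bitwOr(mask, bit)) -
                target) < eps) {
          out[[length(out) + 1L]] <- data.frame(
            cluster_id_A = row_ids[rows[i]], cluster_id_B = col_ids[cols[jj]],
            score = score[rows[i], cols[jj]], stringsAsFactors = FALSE)
          mask <- bitwOr(mask, bit)
          matched <- TRUE
          break
        }
      }
      if (!matched) next
    }
  }
  if (!length(out)) {
    return(data.frame(cluster_id_A = character(0),
                      cluster_id_B = character(0), score = numeric(0)))
  }
  do.call(rbind, out)
}

#' Infer the conserved cluster pairs between two inventories
#'
#' Computes all pairwise [cluster_similarity()] scores, keeps pairs scoring
#' at least `threshold`, and returns the one-to-one assignment maximizing
#' total similarity (exact maximum-weight bipartite matching), with
#' deterministic lexicographic tie-breaking on cluster ids.
#'
#' @param invA,invB `bgc_inventory` objects.
#' @param threshold minimum similarity for a pair to be considered
#'   conserved, in `(0, 1]`. The default 0.7 separates architecture
#'   conservation from within-type background similarity on real
#'   *Streptomyces* inventories.
#' @return a `bgc_conservation_map` with `source = "inferred"`.
#' @export
infer_conservation <- function(invA, invB, threshold = 0.7) {
  stopifnot(threshold > 0, threshold <= 1)
  idsA <- cluster_ids(invA); idsB <- cluster_ids(invB)
  if (!length(idsA) || !length(idsB)) {
    return(conservation_map(
      data.frame(cluster_id_A = character(0), cluster_id_B = character(0),
                 score = numeric(0)), source = "inferred"))
  }
  sigsA <- lapply(invA$clusters, cluster_sig)
  sigsB <- lapply(invB$clusters, cluster_sig)
  typesA <- vapply(invA$clusters, `[[`, character(1), "ctype")
  typesB <- vapply(invB$clusters, `[[`, character(1), "ctype")
  S <- matrix(0, length(idsA), length(idsB), dimnames = list(idsA, idsB))
  for (i in seq_along(idsA)) {
    for (j in seq_along(idsB)) {
      if (typesA[i] == typesB[j]) {
        S[i, j] <- sig_similarity(sigsA[[i]], sigsB[[j]])
      }
    }
  }
  S[S < threshold] <- 0
  conservation_map(max_weight_matching(S, idsA, idsB), source = "inferred")
}

#' Conserved/specific partition and the RC statistic
#'
#' Given two inventories and a conservation map (expert-given or inferred),
#' partitions each strain's clusters into shared and strain-specific sets
#' and computes RC (%) = 2 * Cab / (A + B) * 100 together with per-strain
#' shared/specific fractions. Exact values are kept alongside integer-
#' rounded percentages (the reporting convention of comparative BGC tables).
#'
#' @param invA,invB `bgc_inventory` objects.
#' @param cmap a `bgc_conservation_map`; defaults to
#'   `infer_conservation(invA, invB)`.
#' @return a `bgc_comparison` object (see Details for fields).
#' @details Fields: `A`, `B`, `Cab` (counts), `RC_exact`/`RC` (exact and
#'   rounded percent), `sharedA`, `specificA`, `sharedB`, `specificB` (id
#'   vectors), and exact plus rounded `fracShared`/`fracSpecific` per strain.
#' @export
compute_rc <- function(invA, invB, cmap = NULL) {
  if (is.null(cmap)) cmap <- infer_conservation(invA, invB)
  idsA <- cluster_ids(invA); idsB <- cluster_ids(invB)
  bad <- c(setdiff(cmap$cluster_id_A, idsA), setdiff(cmap$cluster_id_B, idsB))
  if (length(bad)) {
    bgc_stop("bgcrep_unknown_cluster_id",
             sprintf("conservation map references unknown cluster id(s): %s",
                     paste(bad, collapse = ", ")))
  }
  A <- length(idsA); B <- length(idsB); Cab <- nrow(cmap)
  stopifnot(Cab <= min(A, B))
  rc_exact <- if (A + B > 0) 2 * Cab / (A + B) * 100 else NA_real_
  frac <- function(k, n) if (n > 0) 100 * k / n else NA_real_
  res <- list(
    strainA = invA$strain_id, strainB = invB$strain_id,
    A = A, B = B, Cab = Cab,
    RC_exact = rc_exact, RC = round_half_up(rc_exact),
    sharedA = sort(cmap$cluster_id_A),
    specificA = sort(setdiff(idsA, cmap$cluster_id_A)),
    sharedB = sort(cmap$cluster_id_B),
    specificB = sort(setdiff(idsB, cmap$cluster_id_B)),
    fracSharedA_exact = frac(Cab, A),
    fracSpecificA_exact = frac(A - Cab, A),
    fracSharedB_exact = frac(Cab, B),
    fracSpecificB_exact = frac(B - Cab, B),
    map = cmap)
  res$fracSharedA <- round_half_up(res$fracSharedA_exact)
  res$fracSpecificA <- round_half_up(res$fracSpecificA_exact)
  res$fracSharedB <- round_half_up(res$fracSharedB_exact)
  res$fracSpecificB <- round_half_up(res$fracSpecificB_exact)
  structure(res, class = "bgc_comparison")
}

#' @export
print.bgc_comparison <- function(x, ...) {
  cat(sprintf("<bgc_comparison> %s (A=%d) vs %s (B=%d)\n",
              x$strainA, x$A, x$strainB, x$B))
  cat(sprintf("  conserved Cab=%d   RC = %d%% (%.2f exact)\n",
              x$Cab, x$RC, x$RC_exact))
  cat(sprintf("  %s: %d shared (%d%%) / %d specific (%d%%)\n",
              x$strainA, x$Cab, x$fracSharedA, x$A - x$Cab, x$fracSpecificA))
  cat(sprintf("  %s: %d shared (%d%%) / %d specific (%d%%)\n",
              x$strainB, x$Cab, x$fracSharedB, x$B - x$Cab, x$fracSpecificB))
  cat(sprintf("  shared: %s\n", paste(x$sharedA, collapse = ", ")))
  cat(sprintf("  %s-specific: %s\n", x$strainA,
              paste(x$specificA, collapse = ", ")))
  cat(sprintf("  %s-specific: %s\n", x$strainB,
              paste(x$specificB, collapse = ", ")))
  invisible(x)
}
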