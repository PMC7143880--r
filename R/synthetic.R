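# Synthetic strain-pair inventories with known ground truth. The generator
# emulates the statistical structure of real paired Streptomyces
# inventories: two strains of roughly 9 and 13 PKS/NRPS clusters sharing a
# handful of them, a mix of cluster types dominated by type I PKS and NRPS,
# 1-10 modules per synthase gene, and frequent uncalled A-domain substrates.
# Shared clusters are copied between strains and mutated at a tunable
# per-module divergence rate; strain-specific clusters are drawn
# independently and rejection-sampled to be architecturally distinct, so the
# true conserved set is well defined.

#' Configuration for the synthetic strain-pair generator
#'
#' @param nA,nB cluster counts of the two strains (defaults 9 and 13, the
#'   sizes of the motivating real strain pair).
#' @param nShared number of truly conserved clusters (default 5).
#' @param type_weights sampling probabilities over cluster types, default
#'   proportional to the observed type mix of the real pair.
#' @param module_count_mean mean modules per NRPS/type I PKS gene (shifted
#'   Poisson, minimum 1; default 3).
#' @param p_unknown_substrate probability that an A domain carries no
#'   substrate call (default 0.3, the rough rate seen in real tables).
#' @param divergence per-module mutation probability applied to the second
#'   strain's copy of each shared cluster (substrate swap, accessory-domain
#'   gain/loss, module insertion/deletion; type-preserving).
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the config.
#' @return a `bgc_generator_config` list.
#' @export
generator_config <- function(nA = 9, nB = 13, nShared = 5,
                             type_weights = c(t1pks = 0.27, t2pks = 0.18,
                                              t3pks = 0.09, nrps = 0.28,
                                              pks_nrps = 0.18),
                             module_count_mean = 3,
                             p_unknown_substrate = 0.3,
                             divergence = 0, seed = 1) {
  if (nShared > min(nA, nB)) {
    bgc_stop("bgcrep_config_error", "nShared must be <= min(nA, nB)")
  }
  if (abs(sum(type_weights) - 1) > 1e-6 || any(type_weights < 0)) {
    bgc_stop("bgcrep_config_error", "type_weights must be probabilities summing to 1")
  }
  if (any(c(p_unknown_substrate, divergence) < 0) ||
      any(c(p_unknown_substrate, divergence) > 1)) {
    bgc_stop("bgcrep_config_error", "rates must lie in [0, 1]")
  }
  stopifnot(all(names(type_weights) %in% CLUSTER_TYPES))
  structure(list(nA = nA, nB = nB, nShared = nShared,
                 type_weights = type_weights,
                 module_count_mean = module_count_mean,
                 p_unknown_substrate = p_unknown_substrate,
                 divergence = divergence, seed = as.integer(seed)),
            class = "bgc_generator_config")
}

rand_substrate <- function(p_unknown) {
  if (stats::runif(1) < p_unknown) NA_character_
  else sample(RESIDUE_CODES, 1)
}

# one type I PKS extension module with a random reductive loop
rand_pks_module <- function() {
  loop <- sample(c("none", "KR", "DH_KR", "DH_ER_KR"), 1,
                 prob = c(0.15, 0.3, 0.3, 0.25))
  doms <- c("KS", "AT",
            switch(loop, none = character(0), KR = "KR",
                   DH_KR = c("DH", "KR"), DH_ER_KR = c("DH", "ER", "KR")),
            "ACP")
  new_module(lapply(doms, domain_token))
}

rand_nrps_module <- function(first, p_unknown) {
  doms <- list()
  if (!first) doms <- c(doms, list(domain_token("C")))
  sub <- rand_substrate(p_unknown)
  doms <- c(doms, list(domain_token("A", sub)))
  if (stats::runif(1) < 0.1) doms <- c(doms, list(domain_token("MT")))
  doms <- c(doms, list(domain_token("T")))
  if (stats::runif(1) < 0.2) doms <- c(doms, list(domain_token("E")))
  new_module(doms)
}

rand_module_count <- function(mean) 1 + stats::rpois(1, max(mean - 1, 0))

rand_cluster <- function(ctype, cid, locus_prefix, cfg) {
  mk_orf <- function(k, mods) bgc_orf(sprintf("%s_%02d", locus_prefix, k), mods)
  if (ctype == "t3pks") {
    orfs <- list(mk_orf(1, list(new_module(list(domain_token("KS"))))))
  } else if (ctype == "t2pks") {
    orfs <- list(
      mk_orf(1, list(new_module(list(domain_token("KSalpha"))))),
      mk_orf(2, list(new_module(list(domain_token("KSbeta_CLF"))))),
      mk_orf(3, list(new_module(list(domain_token("ACP"))))))
    if (stats::runif(1) < 0.3) {
      orfs <- c(orfs, list(mk_orf(4, list(new_module(list(domain_token("AT")))))))
    }
  } else if (ctype == "t1pks") {
    n_orf <- sample(1:3, 1)
    orfs <- lapply(seq_len(n_orf), function(k) {
      mods <- lapply(seq_len(rand_module_count(cfg$module_count_mean)),
                     function(i) rand_pks_module())
      if (k == n_orf && stats::runif(1) < 0.5) {
        mods <- c(mods, list(new_module(list(domain_token("TE")))))
      }
      mk_orf(k, mods)
    })
  } else if (ctype == "nrps") {
    n_orf <- sample(1:3, 1)
    orfs <- lapply(seq_len(n_orf), function(k) {
      nm <- rand_module_count(cfg$module_count_mean)
      mods <- lapply(seq_len(nm), function(i)
        rand_nrps_module(first = (k == 1 && i == 1), cfg$p_unknown_substrate))
      if (k == n_orf && stats::runif(1) < 0.6) {
        mods <- c(mods, list(new_module(list(domain_token("TE")))))
      }
      mk_orf(k, mods)
    })
  } else { # pks_nrps: an NRPS gene followed by a PKS gene
    nm1 <- rand_module_count(cfg$module_count_mean)
    mods1 <- lapply(seq_len(nm1), function(i)
      rand_nrps_module(first = (i == 1), cfg$p_unknown_substrate))
    nm2 <- rand_module_count(cfg$module_count_mean)
    mods2 <- lapply(seq_len(nm2), function(i) rand_pks_module())
    if (stats::runif(1) < 0.5) {
      mods2 <- c(mods2, list(new_module(list(domain_token("TE")))))
    }
    orfs <- list(mk_orf(1, mods1), mk_orf(2, mods2))
  }
  bgc_cluster(cid, ctype, orfs)
}

# type-preserving mutation of one cluster at per-module rate `rate`
mutate_cluster <- function(cl, rate, cfg) {
  if (rate <= 0) return(cl)
  for (oi in seq_along(cl$orfs)) {
    mods <- cl$orfs[[oi]]$modules
    out <- list()
    for (m in mods) {
      if (stats::runif(1) >= rate) {
        out <- c(out, list(m))
        next
      }
      op <- sample(c("swap_substrate", "toggle_domain", "delete", "insert"), 1)
      kinds <- module_kinds(m)
      if (op == "swap_substrate" && "A" %in% kinds) {
        sub <- rand_substrate(cfg$p_unknown_substrate)
        m$domains <- lapply(m$domains, function(d) {
          if (d$kind == "A") domain_token("A", sub) else d
        })
        out <- c(out, list(m))
      } else if (op == "toggle_domain") {
        acc <- if ("KS" %in% kinds) c("DH", "ER", "KR") else c("E", "MT")
        pick <- sample(acc, 1)
        if (pick %in% kinds) {
          m$domains <- m$domains[kinds != pick]
        } else {
          m$domains <- c(m$domains, list(domain_token(pick)))
        }
        if (length(m$domains)) out <- c(out, list(m))
      } else if (op == "delete") {
        # module dropped, unless it is the gene's only module
        if (length(mods) == 1) out <- c(out, list(m))
      } else { # insert a fresh module of the matching chemistry
        ins <- if ("KS" %in% kinds) rand_pks_module()
               else rand_nrps_module(first = FALSE, cfg$p_unknown_substrate)
        out <- c(out, list(m), list(ins))
      }
    }
    if (!length(out)) out <- mods[1]  # a gene keeps at least one module
    cl$orfs[[oi]]$modules <- out
  }
  cl
}

next_id <- function(counts, ctype) {
  counts[[ctype]] <- (counts[[ctype]] %||% 0L) + 1L
  label <- if (ctype == "pks_nrps") "pks/nrps" else ctype
  list(counts = counts, id = sprintf("%s-%d", label, counts[[ctype]]))
}

#' Generate a synthetic strain pair with known conservation truth
#'
#' Shared clusters are generated once, copied to both strains under the
#' same cluster id, and the second strain's copy is mutated at the
#' configured divergence rate. Strain-specific clusters are drawn
#' independently and rejection-sampled until their architecture similarity
#' to every cluster of the other strain is below 0.5, keeping the ground
#' truth unambiguous. Deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return a list with `invA`, `invB` (`bgc_inventory`) and `truth` (the
#'   config echo, `true_map` data frame, `expected_RC`).
#' @export
generate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "bgc_generator_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  countsA <- list(); countsB <- list()
  clustersA <- list(); clustersB <- list()
  true_map <- list()
  types <- names(cfg$type_weights)
  draw_type <- function() sample(types, 1, prob = cfg$type_weights)
  k <- 0L
  # shared clusters: same id in both strains
  for (s in seq_len(cfg$nShared)) {
    ct <- draw_type()
    tmp <- next_id(countsA, ct); countsA <- tmp$counts
    countsB <- next_id(countsB, ct)$counts
    k <- k + 1L
    base <- rand_cluster(ct, tmp$id, sprintf("SHARED%02d", k), cfg)
    clustersA <- c(clustersA, list(base))
    clustersB <- c(clustersB, list(mutate_cluster(base, cfg$divergence, cfg)))
    true_map[[length(true_map) + 1L]] <- data.frame(
      cluster_id_A = tmp$id, cluster_id_B = tmp$id, stringsAsFactors = FALSE)
  }
  # strain-specific clusters, kept dissimilar (< 0.5) to the other strain
  draw_specific <- function(counts, against, prefix, n_needed) {
    against_sigs <- lapply(against, cluster_sig)
    against_types <- vapply(against, `[[`, character(1), "ctype")
    out <- list()
    rounds <- 0L
    while (length(out) < n_needed) {
      rounds <- rounds + 1L
      if (rounds > 40L * max(n_needed, 1L)) {
        bgc_stop("bgcrep_config_error",
                 "cannot draw enough architecturally distinct specific clusters under these type_weights")
      }
      ok <- FALSE
      for (attempt in 1:25) {
        ct <- draw_type()
        cand <- rand_cluster(ct, "tmp", sprintf("%s%02d", prefix,
                                                length(out) + 1L), cfg)
        cand_sig <- cluster_sig(cand)
        same_type <- which(against_types == ct)
        sims <- vapply(against_sigs[same_type], function(sig)
          sig_similarity(cand_sig, sig), numeric(1))
        if (!length(sims) || max(sims) < 0.5) { ok <- TRUE; break }
      }
      if (!ok) next  # resample type and retry
      tmp <- next_id(counts, ct); counts <- tmp$counts
      cand$cluster_id <- tmp$id
      out <- c(out, list(cand))
      against_sigs <- c(against_sigs, list(cand_sig))
      against_types <- c(against_types, ct)
    }
    list(clusters = out, counts = counts)
  }
  spA <- draw_specific(countsA, clustersB, "SPA", cfg$nA - cfg$nShared)
  clustersA <- c(clustersA, spA$clusters)
  spB <- draw_specific(countsB, clustersA, "SPB", cfg$nB - cfg$nShared)
  clustersB <- c(clustersB, spB$clusters)
  true_map <- if (length(true_map)) do.call(rbind, true_map) else
    data.frame(cluster_id_A = character(0), cluster_id_B = character(0))
  list(invA = bgc_inventory("synthA", clustersA, check_types = FALSE),
       invB = bgc_inventory("synthB", clustersB, check_types = FALSE),
       truth = list(config = cfg,
                    true_map = true_map,
                    expected_RC = 2 * cfg$nShared / (cfg$nA + cfg$nB) * 100))
}

#' Conservation-recovery curve over a divergence grid
#'
#' For each configuration, generates `replicates` strain pairs on a fixed
#' seed schedule (`cfg$seed + replicate - 1`), infers conservation at the
#' given threshold and averages the inferred RC.
#'
#' @param cfg_grid list of [generator_config()] objects (typically varying
#'   `divergence`).
#' @param replicates replicates per configuration (>= 1).
#' @param threshold similarity threshold passed to [infer_conservation()].
#' @return data frame with columns `divergence`, `mean_inferred_RC`,
#'   `true_RC`.
#' @export
recovery_curve <- function(cfg_grid, replicates = 1, threshold = 0.7) {
  stopifnot(replicates >= 1)
  rows <- lapply(cfg_grid, function(cfg) {
    rcs <- vapply(seq_len(replicates), function(r) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r - 1L
      gp <- generate_pair(cfg_r)
      cmap <- infer_conservation(gp$invA, gp$invB, threshold = threshold)
      compute_rc(gp$invA, gp$invB, cmap)$RC_exact
    }, numeric(1))
    data.frame(divergence = cfg$divergence,
               mean_inferred_RC = mean(rcs),
               true_RC = 2 * cfg$nShared / (cfg$nA + cfg$nB) * 100)
  })
  do.call(rbind, rows)
}
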