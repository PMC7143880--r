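# shared helpers: fixture loaders, a grammar sampler for round-trip
# properties, a brute-force matching oracle, and sequence mutators

tp_inventory <- function() example_inventory("TP-A0598")
nbrc_inventory <- function() example_inventory("NBRC3934")

# random domain-organization string drawn from the grammar (canonical and
# markdown-escaped dialects, substrates, type II spellings, "..." gaps)
rand_domain_string <- function() {
  simple <- c("KS", "AT", "DH", "ER", "KR", "ACP", "C", "T", "E", "MT",
              "TE", "TD", "CoL", "DHB")
  rand_tok <- function() {
    r <- runif(1)
    if (r < 0.15) {
      sub <- sample(c("leu", "val", "asp", "thr", "orn", "gly", "ser",
                      "arg", "pro", "pip"), 1)
      carrier <- sample(c("A", "T"), 1, prob = c(0.8, 0.2))
      sample(c(sprintf("%s(%s)", carrier, sub),
               sprintf("%s_(%s)_", carrier, sub)), 1)
    } else if (r < 0.20) {
      sample(c("A", "KSalpha", "KSa", "KSbeta_CLF", "KSb(CLF)", "..."), 1)
    } else {
      sample(simple, 1)
    }
  }
  n_mod <- sample(1:5, 1)
  paste(vapply(seq_len(n_mod), function(i) {
    paste(vapply(seq_len(sample(1:6, 1)), function(j) rand_tok(),
                 character(1)), collapse = "/")
  }, character(1)), collapse = "-")
}

# brute-force maximum-weight one-to-one assignment by permutation search;
# returns the maximal total score over all injective row->column maps
brute_force_matching_total <- function(S, threshold) {
  S[S < threshold] <- 0
  n1 <- nrow(S); n2 <- ncol(S)
  cols <- seq_len(n2)
  best <- 0
  # enumerate injective assignments of rows to columns-or-unmatched (0)
  rec <- function(i, used, total) {
    if (i > n1) { best <<- max(best, total); return(invisible()) }
    rec(i + 1, used, total)
    for (j in setdiff(cols, used)) {
      if (S[i, j] > 0) rec(i + 1, c(used, j), total + S[i, j])
    }
  }
  rec(1, integer(0), 0)
  best
}

# deterministic point mutations in the first k positions of a sequence
mutate_seq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  if (k > 0) {
    v[seq_len(k)] <- vapply(v[seq_len(k)],
                            function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                            character(1))
  }
  paste(v, collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
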