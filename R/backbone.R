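# Backbone prediction by the colinearity rule: an assembly line's product
# mirrors its module order, each NRPS module contributing one amino acid and
# each type I PKS extension module one polyketide-derived unit. Placeholders
# follow the field's table conventions: "x" = amino acid whose A-domain
# substrate is uncalled, "y" = building block of a module lacking an A
# domain, "mx" = N-methylated amino acid (MT domain present), "pk" =
# polyketide-derived moiety.

MODULE_CLASSES <- c("NRPS_EXT", "NRPS_LOAD", "NRPS_NO_A", "PKS_EXT",
                    "PKS_LOAD", "TERMINATION_ONLY", "FRAGMENT")

NRPS_CLASSES <- c("NRPS_EXT", "NRPS_LOAD", "NRPS_NO_A")

#' Classify a module by its domain content
#'
#' A pure function of the domain set: `NRPS_EXT` (C + A + T), `NRPS_LOAD`
#' (A + T, no C; MT tolerated), `NRPS_NO_A` (C + T, no A, no KS), `PKS_EXT`
#' (contains KS), `PKS_LOAD` (CoA-ligase loading didomain), `TERMINATION_ONLY`
#' (only TE/TD), otherwise `FRAGMENT` (lone A, lone ACP, partial reductive
#' loops and the like).
#'
#' @param m a `bgc_module`.
#' @return one of `NRPS_EXT`, `NRPS_LOAD`, `NRPS_NO_A`, `PKS_EXT`,
#'   `PKS_LOAD`, `TERMINATION_ONLY`, `FRAGMENT`.
#' @export
classify_module <- function(m) {
  k <- module_kinds(m)
  has <- function(x) x %in% k
  if (has("A") && has("T")) {
    return(if (has("C")) "NRPS_EXT" else "NRPS_LOAD")
  }
  if (has("C") && has("T") && !has("KS")) return("NRPS_NO_A")
  if (has("KS")) return("PKS_EXT")
  if (has("CoL")) return("PKS_LOAD")
  if (length(k) > 0 && all(k %in% c("TE", "TD"))) return("TERMINATION_ONLY")
  "FRAGMENT"
}

orf_module_classes <- function(orf) {
  vapply(orf$modules, classify_module, character(1))
}

#' Classify a gene cluster by type
#'
#' `t2pks` when dissociated KSalpha + KSbeta(CLF) subunits are present;
#' `t3pks` when the cluster is a single standalone-KS ORF; `pks_nrps` when
#' both PKS and NRPS modules occur; `nrps` when only NRPS modules occur;
#' `t1pks` otherwise (multidomain KS/AT ORFs).
#'
#' @param cl a `bgc_cluster`.
#' @return a cluster type string.
#' @export
classify_cluster <- function(cl) {
  if (!length(cl$orfs)) {
    bgc_stop("bgcrep_no_synthase_domains",
             sprintf("cluster '%s' has no ORFs", cl$cluster_id))
  }
  all_kinds <- unlist(lapply(cl$orfs, function(o)
    unlist(lapply(o$modules, module_kinds))))
  if ("KSalpha" %in% all_kinds && "KSbeta_CLF" %in% all_kinds) return("t2pks")
  if (!any(all_kinds %in% c("KS", "KSalpha", "C", "A", "T"))) {
    bgc_stop("bgcrep_no_synthase_domains",
             sprintf("cluster '%s' contains no synthase domains (KS/C/A/T)",
                     cl$cluster_id))
  }
  if (length(cl$orfs) == 1 && length(cl$orfs[[1]]$modules) == 1 &&
      identical(module_kinds(cl$orfs[[1]]$modules[[1]]), "KS")) {
    return("t3pks")
  }
  classes <- unlist(lapply(cl$orfs, orf_module_classes))
  has_nrps <- any(classes %in% NRPS_CLASSES)
  has_pks <- any(classes %in% c("PKS_EXT", "PKS_LOAD"))
  if (has_nrps && has_pks) return("pks_nrps")
  if (has_nrps) return("nrps")
  "t1pks"
}

#' Order a cluster's ORFs along the assembly line
#'
#' @param cl a `bgc_cluster`.
#' @param mode `"auto"` uses the cluster's explicit `assembly_order` when
#'   present and file order otherwise; `"file_order"` keeps table order;
#'   `"explicit"` requires `assembly_order`; `"heuristic"` moves the ORF
#'   whose first module is a loading module to the front and the TE/TD-
#'   terminated ORF to the back, keeping file order otherwise.
#' @return the list of ORFs in walking order.
#' @export
order_assembly_line <- function(cl, mode = c("auto", "file_order",
                                             "explicit", "heuristic")) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    mode <- if (is.null(cl$assembly_order)) "file_order" else "explicit"
  }
  tags <- vapply(cl$orfs, `[[`, character(1), "locus_tag")
  if (mode == "file_order") return(cl$orfs)
  if (mode == "explicit") {
    if (is.null(cl$assembly_order)) {
      bgc_stop("bgcrep_missing_explicit_order",
               sprintf("cluster '%s' has no assembly_order", cl$cluster_id))
    }
    return(cl$orfs[match(cl$assembly_order, tags)])
  }
  # heuristic: loading ORF first, releasing ORF last, stable otherwise
  first_class <- vapply(cl$orfs, function(o)
    classify_module(o$modules[[1]]), character(1))
  has_release <- vapply(cl$orfs, function(o) {
    any(unlist(lapply(o$modules, module_kinds)) %in% c("TE", "TD"))
  }, logical(1))
  key <- rep(1L, length(cl$orfs))
  key[first_class %in% c("NRPS_LOAD", "PKS_LOAD")] <- 0L
  key[has_release] <- 2L
  cl$orfs[order(key, seq_along(cl$orfs))]
}

residue_label <- function(code) {
  paste0(toupper(substring(code, 1, 1)), substring(code, 2))
}

new_residue <- function(kind, residue = NA_character_) {
  list(kind = kind, residue = residue)
}

residue_string <- function(tok) {
  switch(tok$kind,
         AA = residue_label(tok$residue),
         X = "x", Y = "y", MX = "mx", PK = "pk")
}

#' Predict the product backbone of an assembly-line cluster
#'
#' Walks the modules in assembly-line order and emits one building-block
#' token per biosynthetic module: the A-domain substrate where called
#' (`Leu`, `Val`, ...), `x` for an uncalled substrate, `mx` when an MT
#' domain methylates the residue, `y` for a module lacking an A domain and
#' `pk` for a type I PKS extension module. Epimerization (E) and chain
#' release (TE/TD) domains add nothing. A new chain starts when a loading
#' module follows a released (TE/TD-terminated) segment, as in clusters
#' encoding two independent assembly lines. A standalone A-domain ORF is
#' fused into the next T-carrying module (in trans loading). The final chain
#' is flagged partial when the last walked ORF lacks a release domain and
#' the cluster (or one of its ORFs) is incompletely sequenced.
#'
#' Dissociated type II and standalone type III PKS clusters have no
#' assembly line to walk and are rejected.
#'
#' @param cl a `bgc_cluster` of type `nrps`, `pks_nrps` or `t1pks`.
#' @param mode ORF ordering mode, see [order_assembly_line()].
#' @return a `bgc_backbone` object with elements `chains` (list of residue
#'   token lists) and `chain_partial` (logical per chain).
#' @examples
#' cl <- bgc_cluster("nrps-demo", "nrps", list(
#'   bgc_orf("orfA", parse_domain_string("C/A/T-C/A(leu)/T-TE"))))
#' format(predict_backbone(cl))
#' @export
predict_backbone <- function(cl, mode = "auto") {
  ctype <- classify_cluster(cl)
  if (ctype %in% c("t2pks", "t3pks")) {
    bgc_stop("bgcrep_not_an_assembly_line",
             sprintf("cluster '%s' is %s: no colinear assembly line to walk",
                     cl$cluster_id, ctype))
  }
  orfs <- order_assembly_line(cl, mode)
  chains <- list()
  current <- list()
  released <- FALSE   # has the running chain been TE/TD-released?
  emit <- function(tok, load_class) {
    if (load_class && released && length(current)) {
      chains[[length(chains) + 1L]] <<- current
      current <<- list()
    }
    released <<- FALSE
    current[[length(current) + 1L]] <<- tok
  }
  for (i in seq_along(orfs)) {
    orf <- orfs[[i]]
    mods <- orf$modules
    classes <- vapply(mods, classify_module, character(1))
    # standalone A-domain ORF feeding the next ORF's T-carrying module
    if (length(mods) == 1 && classes[1] == "FRAGMENT" &&
        identical(module_kinds(mods[[1]]), "A") && i < length(orfs)) {
      nxt <- orfs[[i + 1]]$modules[[1]]
      if ("T" %in% module_kinds(nxt)) {
        sub <- mods[[1]]$domains[[1]]$substrate
        emit(if (is.na(sub)) new_residue("X") else new_residue("AA", sub),
             load_class = TRUE)
        next
      }
    }
    for (j in seq_along(mods)) {
      m <- mods[[j]]
      cls <- classes[j]
      kinds <- module_kinds(m)
      if (cls %in% c("NRPS_EXT", "NRPS_LOAD")) {
        sub <- module_substrate(m)
        tok <- if (!is.na(sub)) new_residue("AA", sub)
               else if ("MT" %in% kinds) new_residue("MX")
               else new_residue("X")
        emit(tok, load_class = cls == "NRPS_LOAD")
      } else if (cls == "NRPS_NO_A") {
        emit(new_residue("Y"), load_class = FALSE)
      } else if (cls == "PKS_EXT") {
        emit(new_residue("PK"), load_class = FALSE)
      }
      # PKS_LOAD primes the line but contributes no backbone unit;
      # TERMINATION_ONLY and FRAGMENT modules emit nothing
      if (any(kinds %in% c("TE", "TD"))) released <- TRUE
    }
  }
  if (length(current)) chains[[length(chains) + 1L]] <- current
  if (!length(chains)) {
    bgc_stop("bgcrep_not_an_assembly_line",
             sprintf("cluster '%s' contains no backbone-emitting modules",
                     cl$cluster_id))
  }
  any_incomplete <- cl$partial ||
    any(vapply(orfs, `[[`, logical(1), "incomplete"))
  last_kinds <- unlist(lapply(orfs[[length(orfs)]]$modules, module_kinds))
  last_released <- any(last_kinds %in% c("TE", "TD"))
  chain_partial <- rep(FALSE, length(chains))
  chain_partial[length(chains)] <- !last_released && any_incomplete
  structure(list(cluster_id = cl$cluster_id, chains = chains,
                 chain_partial = chain_partial),
            class = "bgc_backbone")
}

#' Format a backbone prediction as the conventional product string
#'
#' Residues are joined with `-`, independent chains with `", "`, and a
#' trailing `-` marks an open-ended (partially sequenced) chain, e.g.
#' `"mx-x-Gly-"` or `"Thr-Thr-x, Arg-Pro"`.
#'
#' @param x a `bgc_backbone` from [predict_backbone()].
#' @param ... unused.
#' @return a single string.
#' @export
format.bgc_backbone <- function(x, ...) {
  paste(mapply(function(chain, partial) {
    paste0(paste(vapply(chain, residue_string, character(1)), collapse = "-"),
           if (partial) "-" else "")
  }, x$chains, x$chain_partial), collapse = ", ")
}

#' @export
print.bgc_backbone <- function(x, ...) {
  cat(sprintf("<backbone %s> %s\n", x$cluster_id, format(x)))
  invisible(x)
}
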