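# Domain-organization string grammar for assembly-line synthases.
#
# A gene's catalytic domain organization is written the way comparative BGC
# papers print it: domains joined by "/" within a module, modules joined by
# "-", and adenylation-domain substrate calls in parentheses, e.g.
#   "A(asp)/T-C/A(asn)/T-C/A(leu)/T"
# is a three-module NRPS. "..." marks a stretch of undetermined domains.

# closed enumeration of domain codes (canonical spellings)
DOMAIN_KINDS <- c(
  "KS", "AT", "DH", "ER", "KR", "ACP",       # type I PKS
  "KSalpha", "KSbeta_CLF",                   # type II PKS
  "C", "A", "T", "E", "MT",                  # NRPS
  "TE", "TD",                                # chain release
  "CoL",                                     # CoA ligase loading didomain
  "DHB",                                     # dihydroxybenzoate activation
  "GAP"                                      # "..." undetermined stretch
)

# substrate residue codes seen in adenylation/thiolation annotations
RESIDUE_CODES <- c(
  "leu", "val", "asp", "asn", "phe", "thr", "ala",
  "orn", "gly", "ser", "arg", "pro", "pip"
)

#' Constructor for a single domain token
#'
#' @param kind canonical domain code (one of the closed enumeration, e.g.
#'   `"KS"`, `"A"`, `"KSbeta_CLF"`, `"GAP"`).
#' @param substrate optional lowercase residue code attached to an A or T
#'   domain (e.g. `"leu"`), or `NA`.
#' @return a `bgc_domain` object.
#' @export
domain_token <- function(kind, substrate = NA_character_) {
  if (!kind %in% DOMAIN_KINDS) {
    bgc_stop("bgcrep_unknown_domain_token",
             sprintf("unknown domain token '%s'", kind))
  }
  if (!is.na(substrate) && !kind %in% c("A", "T")) {
    bgc_stop("bgcrep_unknown_domain_token",
             sprintf("substrate annotation is only valid on A or T domains, not '%s'", kind))
  }
  structure(list(kind = kind, substrate = substrate), class = "bgc_domain")
}

# normalize one raw domain token string to (kind, substrate); errors on junk
parse_domain_token <- function(tok) {
  raw <- tok
  tok <- gsub("[[:space:]]+", "", tok)
  if (tok %in% c("…", "...")) return(domain_token("GAP"))
  # type II KS spellings: KSα, KSa, KSalpha, KSβ, KSb, KSbeta, KSbeta(CLF),
  # KSbeta_CLF, with or without the (CLF) qualifier
  if (grepl("^KS(α|a|alpha)$", tok)) return(domain_token("KSalpha"))
  if (grepl("^KS(β|b|beta)(\\(CLF\\)|_CLF)?$", tok)) {
    return(domain_token("KSbeta_CLF"))
  }
  # substrate subscript: canonical "A(leu)"; markdown-escaped "A_(leu)_" and
  # one-sided "T_(thr)" dialects accepted
  m <- regmatches(tok, regexec("^([A-Za-z]+)_?\\(([a-z]+)\\)_?$", tok))[[1]]
  if (length(m) == 3) {
    kind <- m[2]
    if (!kind %in% DOMAIN_KINDS) {
      bgc_stop("bgcrep_unknown_domain_token",
               sprintf("unknown domain token '%s'", raw))
    }
    return(domain_token(kind, m[3]))
  }
  if (tok %in% DOMAIN_KINDS && tok != "GAP") return(domain_token(tok))
  bgc_stop("bgcrep_unknown_domain_token",
           sprintf("unknown domain token '%s'", raw))
}

#' Parse a domain-organization string into modules
#'
#' Splits on `-` (module boundaries) then `/` (domains within a module),
#' exactly as printed; no re-segmentation is attempted. Substrate subscripts
#' may be written `A(leu)` (canonical) or `A_(leu)_` (markdown-escaped
#' table dialect); `KSα`/`KSβ (CLF)` spellings are accepted for the type II
#' PKS subunits, and `...` for an undetermined domain stretch.
#'
#' @param text a non-empty domain-organization string.
#' @return a list of `bgc_module` objects, in gene order.
#' @examples
#' parse_domain_string("C/A(leu)/T")
#' parse_domain_string("A(asp)/T-C/A(asn)/T-C/A(leu)/T")
#' @export
parse_domain_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) {
    bgc_stop("bgcrep_empty_module", "empty domain-organization string")
  }
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(trimws(parts))) || length(parts) == 0) {
    bgc_stop("bgcrep_empty_module",
             sprintf("empty module (consecutive hyphens) in '%s'", text))
  }
  lapply(parts, function(p) {
    toks <- strsplit(p, "/", fixed = TRUE)[[1]]
    if (any(!nzchar(trimws(toks)))) {
      bgc_stop("bgcrep_empty_module",
               sprintf("empty domain token in module '%s'", p))
    }
    new_module(lapply(toks, parse_domain_token))
  })
}

#' @export
print.bgc_domain <- function(x, ...) {
  cat(serialize_domain(x), "\n")
  invisible(x)
}

serialize_domain <- function(d) {
  if (d$kind == "GAP") return("...")
  if (is.na(d$substrate)) d$kind else sprintf("%s(%s)", d$kind, d$substrate)
}

new_module <- function(domains) {
  structure(list(domains = domains), class = "bgc_module")
}

module_kinds <- function(m) vapply(m$domains, `[[`, character(1), "kind")

# the module's substrate call: taken from the A domain, else from a
# substrate-annotated T domain (the printed tables put it on either)
module_substrate <- function(m) {
  subs <- vapply(m$domains, function(d) d$substrate, character(1))
  kinds <- module_kinds(m)
  for (pref in c("A", "T")) {
    i <- which(kinds == pref & !is.na(subs))
    if (length(i)) return(subs[i[1]])
  }
  NA_character_
}

#' Serialize modules back to the canonical domain-organization string
#'
#' Canonical dialect: `/` within modules, `-` between modules, substrates as
#' `A(leu)`, type II PKS subunits as `KSalpha` / `KSbeta_CLF`, undetermined
#' stretches as `...`. `parse_domain_string()` of the output round-trips.
#'
#' @param modules a list of `bgc_module` objects.
#' @return a single string.
#' @export
serialize_modules <- function(modules) {
  paste(vapply(modules, function(m) {
    paste(vapply(m$domains, serialize_domain, character(1)), collapse = "/")
  }, character(1)), collapse = "-")
}

#' @export
print.bgc_module <- function(x, ...) {
  cat("<module>", serialize_modules(list(x)), "\n")
  invisible(x)
}
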