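# Strain cluster inventories: the per-strain table of PKS/NRPS gene clusters,
# one row per ORF, mirroring the layout of published cluster tables
# (cluster id, known product, locus tag, protein size, domain organization).

CLUSTER_TYPES <- c("t1pks", "t2pks", "t3pks", "nrps", "pks_nrps")

INVENTORY_COLUMNS <- c("strain_id", "cluster_id", "ctype", "known_product",
                       "locus_tag", "size_aa", "domain_organization",
                       "assembly_order")

#' Constructor for one open reading frame of a cluster
#'
#' @param locus_tag non-empty locus tag, unique within the cluster.
#' @param modules list of `bgc_module` (from [parse_domain_string()]).
#' @param size_aa protein length in amino acids (descriptive metadata).
#' @param size_is_lower_bound `TRUE` when the printed size carried a `>`
#'   prefix (partially sequenced gene).
#' @param incomplete `TRUE` when the ORF sits at a scaffold terminus and is
#'   not completely sequenced.
#' @return a `bgc_orf` object.
#' @export
bgc_orf <- function(locus_tag, modules, size_aa = NA_integer_,
                    size_is_lower_bound = FALSE, incomplete = FALSE) {
  stopifnot(nzchar(locus_tag), is.list(modules))
  structure(list(locus_tag = locus_tag, modules = modules,
                 size_aa = as.integer(size_aa),
                 size_is_lower_bound = isTRUE(size_is_lower_bound),
                 incomplete = isTRUE(incomplete)),
            class = "bgc_orf")
}

#' Constructor for a gene cluster
#'
#' @param cluster_id cluster identifier (e.g. `"nrps-1"`).
#' @param ctype one of `t1pks`, `t2pks`, `t3pks`, `nrps`, `pks_nrps`
#'   (`"pks/nrps"` is normalized on input).
#' @param orfs list of [bgc_orf()] objects in table order.
#' @param known_product optional product annotation; a value containing
#'   `"partial"` flags the cluster as a partial match to a known BGC.
#' @param assembly_order optional character vector of locus tags giving the
#'   biosynthetic assembly-line order where it differs from table order.
#' @return a `bgc_cluster` object.
#' @export
bgc_cluster <- function(cluster_id, ctype, orfs, known_product = NA_character_,
                        assembly_order = NULL) {
  ctype <- gsub("/", "_", ctype, fixed = TRUE)
  stopifnot(nzchar(cluster_id), ctype %in% CLUSTER_TYPES)
  tags <- vapply(orfs, `[[`, character(1), "locus_tag")
  if (anyDuplicated(tags)) {
    bgc_stop("bgcrep_format_error",
             sprintf("duplicate locus tags in cluster '%s'", cluster_id))
  }
  if (!is.null(assembly_order)) {
    if (!setequal(assembly_order, tags)) {
      bgc_stop("bgcrep_format_error",
               sprintf("assembly_order of '%s' must be a permutation of its locus tags",
                       cluster_id))
    }
  }
  partial <- !is.na(known_product) && grepl("partial", known_product,
                                            ignore.case = TRUE)
  structure(list(cluster_id = cluster_id, ctype = ctype, orfs = orfs,
                 known_product = known_product, partial = partial,
                 assembly_order = assembly_order),
            class = "bgc_cluster")
}

#' Constructor for a strain inventory
#'
#' @param strain_id non-empty strain identifier.
#' @param clusters list of [bgc_cluster()] objects; ids must be unique.
#' @param check_types warn when a declared cluster type disagrees with
#'   [classify_cluster()] on the domain content.
#' @return a `bgc_inventory` object.
#' @export
bgc_inventory <- function(strain_id, clusters = list(), check_types = TRUE) {
  stopifnot(nzchar(strain_id))
  ids <- vapply(clusters, `[[`, character(1), "cluster_id")
  if (anyDuplicated(ids)) {
    bgc_stop("bgcrep_duplicate_cluster_id",
             sprintf("duplicate cluster id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  inv <- structure(list(strain_id = strain_id, clusters = clusters),
                   class = "bgc_inventory")
  if (check_types) {
    for (cl in clusters) {
      inferred <- tryCatch(classify_cluster(cl), error = function(e) NA_character_)
      if (!is.na(inferred) && inferred != cl$ctype) {
        warning(sprintf("cluster '%s' declared %s but classifies as %s",
                        cl$cluster_id, cl$ctype, inferred), call. = FALSE)
      }
    }
  }
  inv
}

cluster_ids <- function(inv) vapply(inv$clusters, `[[`, character(1), "cluster_id")

get_cluster <- function(inv, id) {
  i <- match(id, cluster_ids(inv))
  if (is.na(i)) {
    bgc_stop("bgcrep_unknown_cluster_id",
             sprintf("no cluster '%s' in strain %s", id, inv$strain_id))
  }
  inv$clusters[[i]]
}

#' @export
print.bgc_inventory <- function(x, ...) {
  cat(sprintf("<bgc_inventory> strain %s: %d cluster(s)\n",
              x$strain_id, length(x$clusters)))
  for (cl in x$clusters) {
    cat(sprintf("  %-12s %-8s %2d ORF(s)%s\n", cl$cluster_id, cl$ctype,
                length(cl$orfs),
                if (!is.na(cl$known_product)) paste0("  [", cl$known_product, "]") else ""))
  }
  invisible(x)
}

# parse a printed size such as "1,446" or ">375"
parse_size <- function(s) {
  if (is.na(s) || !nzchar(trimws(s)) || trimws(s) == "NA") {
    return(list(size = NA_integer_, lower_bound = FALSE))
  }
  s <- trimws(s)
  lb <- startsWith(s, ">")
  if (lb) s <- substring(s, 2)
  s <- gsub(",", "", s, fixed = TRUE)
  n <- suppressWarnings(as.integer(s))
  list(size = n, lower_bound = lb)
}

# parse a locus tag, peeling the "^t" scaffold-terminus marker
parse_locus <- function(s) {
  s <- trimws(s)
  inc <- grepl("\\^t$", s)
  list(tag = sub("\\^t$", "", s), incomplete = inc)
}

inventory_from_rows <- function(df, path = "<data>") {
  need <- setdiff(INVENTORY_COLUMNS, c("assembly_order", "known_product"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    bgc_stop("bgcrep_format_error",
             sprintf("%s: missing column(s) %s", path,
                     paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    bgc_stop("bgcrep_format_error", sprintf("%s: no data rows", path))
  }
  strain <- unique(df$strain_id)
  if (length(strain) != 1) {
    bgc_stop("bgcrep_format_error",
             sprintf("%s: expected a single strain_id, got %s", path,
                     paste(strain, collapse = ", ")))
  }
  clusters <- list()
  for (cid in unique(df$cluster_id)) {
    rows <- df[df$cluster_id == cid, , drop = FALSE]
    orfs <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      loc <- parse_locus(r$locus_tag)
      sz <- parse_size(as.character(r$size_aa))
      mods <- withCallingHandlers(
        parse_domain_string(r$domain_organization),
        error = function(e) {
          if (inherits(e, "bgcrep_error")) {
            bgc_stop(class(e)[1],
                     sprintf("%s: cluster %s, locus %s: %s",
                             path, cid, loc$tag, conditionMessage(e)))
          }
        })
      bgc_orf(loc$tag, mods, size_aa = sz$size,
              size_is_lower_bound = sz$lower_bound,
              incomplete = loc$incomplete)
    })
    prod <- rows$known_product[1]
    if (is.null(prod) || is.na(prod) || !nzchar(trimws(prod))) prod <- NA_character_
    ord <- NULL
    if ("assembly_order" %in% names(rows)) {
      ov <- rows$assembly_order[!is.na(rows$assembly_order) &
                                nzchar(trimws(rows$assembly_order))]
      if (length(ov)) ord <- trimws(strsplit(ov[1], ",", fixed = TRUE)[[1]])
    }
    clusters[[length(clusters) + 1L]] <-
      bgc_cluster(cid, rows$ctype[1], orfs, known_product = prod,
                  assembly_order = ord)
  }
  bgc_inventory(strain, clusters)
}

#' Read a strain inventory from TSV or JSON
#'
#' The TSV layout mirrors published cluster tables: columns `strain_id`,
#' `cluster_id`, `ctype`, `known_product`, `locus_tag`, `size_aa`,
#' `domain_organization` and optional `assembly_order`, one row per ORF,
#' `#` comment lines allowed. Sizes may carry a `>` lower-bound prefix and
#' thousands separators; locus tags may carry a `^t` suffix marking an ORF
#' truncated at a scaffold terminus. The JSON format is a field-for-field
#' mirror.
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`; default guesses from the extension.
#' @return a validated `bgc_inventory`.
#' @export
read_inventory <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (!file.exists(path)) {
    bgc_stop("bgcrep_io_error", sprintf("file not found: %s", path))
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    clusters <- lapply(obj$clusters, function(cl) {
      orfs <- lapply(cl$orfs, function(o) {
        bgc_orf(o$locus_tag, parse_domain_string(o$domain_organization),
                size_aa = o$size_aa %||% NA_integer_,
                size_is_lower_bound = isTRUE(o$size_is_lower_bound),
                incomplete = isTRUE(o$incomplete))
      })
      bgc_cluster(cl$cluster_id, cl$ctype, orfs,
                  known_product = cl$known_product %||% NA_character_,
                  assembly_order = unlist(cl$assembly_order) %||% NULL)
    })
    return(bgc_inventory(obj$strain_id, clusters))
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(df) == 0 && ncol(df) >= 2) {
    # header-only file: zero clusters; the strain id comes from a
    # "#strain:" comment line
    hdr <- grep("^#strain:", readLines(path), value = TRUE)
    if (length(hdr) == 1) {
      return(bgc_inventory(trimws(sub("^#strain:", "", hdr))))
    }
    bgc_stop("bgcrep_format_error",
             sprintf("%s: no data rows and no #strain: header", path))
  }
  inventory_from_rows(df, path = path)
}

#' Write a strain inventory to TSV or JSON
#'
#' Serialization is canonical (substrates as `A(leu)`, sizes with `>` for
#' lower bounds, `^t` suffix for scaffold-terminus ORFs), so
#' `read_inventory(write_inventory(inv))` is the identity.
#'
#' @param inv a `bgc_inventory`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`; default guesses from the extension.
#' @return `invisible(path)`.
#' @export
write_inventory <- function(inv, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- list(strain_id = inv$strain_id,
                clusters = lapply(inv$clusters, function(cl) {
      out <- list(cluster_id = cl$cluster_id, ctype = cl$ctype,
                  known_product = cl$known_product,
                  orfs = lapply(cl$orfs, function(o) {
                    list(locus_tag = o$locus_tag,
                         size_aa = o$size_aa,
                         size_is_lower_bound = o$size_is_lower_bound,
                         incomplete = o$incomplete,
                         domain_organization = serialize_modules(o$modules))
                  }))
      if (!is.null(cl$assembly_order)) out$assembly_order <- cl$assembly_order
      out
    }))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  rows <- list()
  for (cl in inv$clusters) {
    ord <- if (is.null(cl$assembly_order)) "" else
      paste(cl$assembly_order, collapse = ",")
    for (i in seq_along(cl$orfs)) {
      o <- cl$orfs[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = inv$strain_id,
        cluster_id = cl$cluster_id,
        ctype = cl$ctype,
        known_product = if (i == 1 && !is.na(cl$known_product)) cl$known_product else "",
        locus_tag = paste0(o$locus_tag, if (o$incomplete) "^t" else ""),
        size_aa = if (is.na(o$size_aa)) "" else
          paste0(if (o$size_is_lower_bound) ">" else "", o$size_aa),
        domain_organization = serialize_modules(o$modules),
        assembly_order = if (i == 1) ord else "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    writeLines(c(sprintf("#strain: %s", inv$strain_id),
                 paste(INVENTORY_COLUMNS, collapse = "\t")), path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# structural equality on the canonical serialization (used by round-trip tests)
inventory_equal <- function(a, b) {
  fa <- tempfile(fileext = ".json"); fb <- tempfile(fileext = ".json")
  on.exit(unlink(c(fa, fb)))
  write_inventory(a, fa, "json"); write_inventory(b, fb, "json")
  identical(readLines(fa), readLines(fb))
}
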