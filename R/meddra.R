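# MedDRA-like adverse event dictionary: five levels, LLT (most specific)
# through SOC (most general), with possibly multi-axial links above PT.

#' Hierarchy levels of a MedDRA-like dictionary
#'
#' Levels ordered from most specific to most general:
#' `LLT < PT < HLT < HLGT < SOC`.
#'
#' @format Character vector of length 5.
#' @export
MEDDRA_LEVELS <- c("LLT", "PT", "HLT", "HLGT", "SOC")

.level_rank <- function(level) {
  r <- match(level, MEDDRA_LEVELS)
  if (anyNA(r)) {
    stop("unknown hierarchy level(s): ",
         paste(unique(level[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r
}

#' Construct and validate a MedDRA-like dictionary
#'
#' Builds a `meddra_dict` from a term table. Every term has a unique code, a
#' level, and parent codes at the next level up. LLTs must have exactly one PT
#' parent; links above PT may be one-to-many (multi-axiality); SOC terms have
#' no parents. The hierarchy is acyclic by construction because every parent
#' link climbs exactly one level.
#'
#' @param terms data.frame with columns `code`, `name`, `level`,
#'   `parent_codes` (codes separated by `"|"`; empty for SOC rows) and
#'   optionally `primary_soc` (for PT rows: the SOC used when counting events
#'   on the primary axis).
#' @return An object of class `meddra_dict`.
#' @export
meddra_dictionary <- function(terms) {
  req <- c("code", "name", "level", "parent_codes")
  miss <- setdiff(req, names(terms))
  if (length(miss)) {
    stop("dictionary table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  terms$code <- as.character(terms$code)
  terms$name <- as.character(terms$name)
  terms$level <- as.character(terms$level)
  terms$parent_codes <- as.character(terms$parent_codes)
  terms$parent_codes[is.na(terms$parent_codes)] <- ""
  if (is.null(terms$primary_soc)) terms$primary_soc <- NA_character_
  terms$primary_soc <- as.character(terms$primary_soc)
  terms$primary_soc[!is.na(terms$primary_soc) & terms$primary_soc == ""] <-
    NA_character_

  rank <- .level_rank(terms$level)
  if (anyDuplicated(terms$code)) {
    stop("duplicated term code(s): ",
         paste(unique(terms$code[duplicated(terms$code)]), collapse = ", "),
         call. = FALSE)
  }

  plist <- strsplit(terms$parent_codes, "|", fixed = TRUE)
  plist <- lapply(plist, function(p) p[nzchar(p)])
  npar <- lengths(plist)
  edges <- data.frame(
    code = rep(terms$code, npar),
    parent = unlist(plist),
    stringsAsFactors = FALSE
  )

  dangling <- setdiff(edges$parent, terms$code)
  if (length(dangling)) {
    stop("dangling parent code(s) not defined in dictionary: ",
         paste(sort(unique(dangling)), collapse = ", "), call. = FALSE)
  }
  is_soc <- terms$level == "SOC"
  if (any(npar[is_soc] > 0L)) {
    stop("SOC term(s) with parents: ",
         paste(terms$code[is_soc & npar > 0L], collapse = ", "), call. = FALSE)
  }
  if (nrow(edges)) {
    child_rank <- rank[match(edges$code, terms$code)]
    parent_rank <- rank[match(edges$parent, terms$code)]
    bad <- parent_rank != child_rank + 1L
    if (any(bad)) {
      stop("parent links must climb exactly one level; offending link(s): ",
           paste(paste0(edges$code[bad], "->", edges$parent[bad]),
                 collapse = ", "), call. = FALSE)
    }
  }
  if (any(npar[!is_soc] == 0L)) {
    stop("non-SOC term(s) without any parent (cannot reach a SOC): ",
         paste(terms$code[!is_soc & npar == 0L], collapse = ", "),
         call. = FALSE)
  }
  is_llt <- terms$level == "LLT"
  if (any(npar[is_llt] != 1L)) {
    stop("LLT term(s) must have exactly one PT parent: ",
         paste(terms$code[is_llt & npar != 1L], collapse = ", "),
         call. = FALSE)
  }
  ps <- terms$primary_soc[!is.na(terms$primary_soc)]
  bad_ps <- setdiff(ps, terms$code[is_soc])
  if (length(bad_ps)) {
    stop("primary_soc value(s) that are not SOC codes: ",
         paste(unique(bad_ps), collapse = ", "), call. = FALSE)
  }

  structure(
    list(terms = terms[, c("code", "name", "level", "parent_codes",
                           "primary_soc")],
         edges = edges),
    class = "meddra_dict"
  )
}

#' Read a dictionary from its CSV serialization
#'
#' Expects one UTF-8 CSV with columns `code,name,level,parent_codes`
#' (and optionally `primary_soc`); `parent_codes` uses `|` as the intra-cell
#' separator.
#'
#' @param path Path to the dictionary CSV.
#' @return A validated `meddra_dict`.
#' @seealso [write_meddra_dictionary()]
#' @export
read_meddra_dictionary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  meddra_dictionary(df)
}

#' Write a dictionary to CSV
#'
#' Round-trips with [read_meddra_dictionary()]: the logical content (terms,
#' levels, links) is reproduced exactly, independent of row order.
#'
#' @param dict A `meddra_dict`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meddra_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "meddra_dict"))
  out <- dict$terms
  out$primary_soc[is.na(out$primary_soc)] <- ""
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

.dict_level <- function(dict, codes) {
  i <- match(codes, dict$terms$code)
  if (anyNA(i)) {
    stop("unknown term code(s): ", paste(codes[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  dict$terms$level[i]
}

#' Ancestors of a term at a chosen hierarchy level
#'
#' Follows parent links upward and returns every code at the target level that
#' is reachable from `code`. At the term's own level the result is the term
#' itself. Multi-axial terms can return more than one ancestor.
#'
#' @param dict A `meddra_dict`.
#' @param code A term code present in the dictionary.
#' @param level Target level, at or above the level of `code`.
#' @return Sorted character vector of ancestor codes.
#' @export
ancestors_at_level <- function(dict, code, level) {
  stopifnot(inherits(dict, "meddra_dict"), length(code) == 1L)
  from <- .level_rank(.dict_level(dict, code))
  to <- .level_rank(level)
  if (to < from) {
    stop("target level ", level, " is below the level of ", code,
         call. = FALSE)
  }
  frontier <- code
  while (from < to) {
    frontier <- unique(dict$edges$parent[dict$edges$code %in% frontier])
    from <- from + 1L
  }
  sort(frontier)
}

# All-pairs ancestor map between two levels: data.frame(code, ancestor),
# one row per reachable (term, ancestor-at-to_level) pair.
.ancestor_map <- function(dict, from_level, to_level) {
  codes <- dict$terms$code[dict$terms$level == from_level]
  map <- data.frame(code = codes, ancestor = codes, stringsAsFactors = FALSE)
  from <- .level_rank(from_level)
  to <- .level_rank(to_level)
  while (from < to) {
    step_codes <- dict$terms$code[.level_rank(dict$terms$level) == from]
    e <- dict$edges[dict$edges$code %in% step_codes, , drop = FALSE]
    i <- match(map$ancestor, e$code)
    if (!anyDuplicated(e$code)) {
      map$ancestor <- e$parent[i]
      map <- map[!is.na(map$ancestor), , drop = FALSE]
    } else {
      m <- merge(map, e, by.x = "ancestor", by.y = "code")
      map <- unique(data.frame(code = m$code, ancestor = m$parent,
                               stringsAsFactors = FALSE))
    }
    from <- from + 1L
  }
  unique(map)
}

# PT -> SOC assignment on the primary axis. PTs lacking an explicit
# primary_soc fall back to their lexicographically first SOC ancestor.
.primary_soc_map <- function(dict) {
  pts <- dict$terms[dict$terms$level == "PT", , drop = FALSE]
  out <- pts$primary_soc
  need <- is.na(out)
  if (any(need)) {
    amap <- .ancestor_map(dict, "PT", "SOC")
    amap <- amap[order(amap$code, amap$ancestor), , drop = FALSE]
    first <- amap[!duplicated(amap$code), , drop = FALSE]
    out[need] <- first$ancestor[match(pts$code[need], first$code)]
  }
  stats::setNames(out, pts$code)
}

#' Terms at a hierarchy level
#'
#' @param dict A `meddra_dict`.
#' @param level One of `r paste(MEDDRA_LEVELS, collapse = ", ")`.
#' @return data.frame of the terms at `level`, sorted by code.
#' @export
terms_at_level <- function(dict, level) {
  stopifnot(inherits(dict, "meddra_dict"))
  .level_rank(level)
  out <- dict$terms[dict$terms$level == level, , drop = FALSE]
  out <- out[order(out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.meddra_dict <- function(x, ...) {
  cnt <- table(factor(x$terms$level, levels = MEDDRA_LEVELS))
  cat("MedDRA-like dictionary:", nrow(x$terms), "terms\n")
  cat(paste(sprintf("  %-4s %d", names(cnt), as.integer(cnt)),
            collapse = "\n"), "\n")
  invisible(x)
}
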