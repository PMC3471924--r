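#' Gene sets and the GMT format
#'
#' A gene set is a named collection of symbols, optionally carrying a
#' per-member direction (+1 up, -1 down) for directed comparisons such as
#' human breast-cancer biomarker sets.  The reader accepts the standard GMT
#' dialect (name, description, tab-separated members) plus a directed
#' dialect in which a member may end in "+" or "-".
#'
#' @param name set name.
#' @param members character vector of gene symbols (deduplicated).
#' @param directions optional named numeric vector of +1/-1, keyed by member.
#' @param description free-text description.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, members, directions = NULL, description = "") {
  members <- unique(as.character(members))
  if (!length(members)) stop_ldsig("gene set '%s' has no members", name)
  if (!is.null(directions)) {
    if (is.null(names(directions)) ||
        !all(names(directions) %in% members)) {
      stop_ldsig("directions must be keyed by set members")
    }
    if (!all(directions %in% c(-1, 1))) {
      stop_ldsig("directions must be +1 or -1")
    }
  }
  structure(list(name = name, description = description,
                 members = members, directions = directions),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members%s\n", x$name, length(x$members),
              if (is.null(x$directions)) "" else " (directed)"))
  invisible(x)
}

#' @rdname gene_set
#' @param path GMT file path.
#' @param directed parse trailing "+"/"-" on members as directions.
#' @return [read_gmt()] returns a list of `gene_set` objects (possibly empty).
#' @export
read_gmt <- function(path, directed = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_ldsig("GMT parse error at line %d: fewer than 3 fields", i)
    }
    members <- fields[-(1:2)]
    directions <- NULL
    if (directed) {
      sign_chr <- substring(members, nchar(members))
      has_sign <- sign_chr %in% c("+", "-")
      stripped <- ifelse(has_sign,
                         substring(members, 1L, nchar(members) - 1L),
                         members)
      keep <- !duplicated(stripped)
      members <- stripped[keep]
      if (any(has_sign)) {
        directions <- ifelse(sign_chr[keep] == "-", -1, 1)
        names(directions) <- members
      }
    }
    out[[i]] <- gene_set(fields[1L], members, directions,
                         description = fields[2L])
  }
  out
}

#' @rdname gene_set
#' @param sets list of `gene_set` objects.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    members <- s$members
    if (!is.null(s$directions)) {
      suffix <- ifelse(s$directions[members] < 0, "-", "+")
      suffix[is.na(suffix)] <- ""
      members <- paste0(members, suffix)
    }
    paste(c(s$name, s$description, members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
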