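#' Ortholog tables and cross-species signature mapping
#'
#' Mouse symbols are title case, human symbols upper case; translation
#' between the species always goes through an ortholog table rather than
#' case-folding equality.  Tables are two-column TSV (mouse_symbol,
#' human_symbol); a mouse symbol may map to several human symbols.
#'
#' @param pairs data.frame with columns `mouse_symbol` and `human_symbol`.
#' @return An `ortholog_table`: a named list mapping each mouse symbol to a
#'   deduplicated character vector of human symbols.
#' @export
ortholog_table <- function(pairs) {
  if (!all(c("mouse_symbol", "human_symbol") %in% names(pairs))) {
    stop_ldsig("pairs needs columns mouse_symbol, human_symbol")
  }
  if (any(!nzchar(pairs$mouse_symbol)) || any(!nzchar(pairs$human_symbol))) {
    stop_ldsig("empty symbol in ortholog table")
  }
  map <- lapply(split(as.character(pairs$human_symbol),
                      as.character(pairs$mouse_symbol)), unique)
  structure(map, class = "ortholog_table")
}

#' @rdname ortholog_table
#' @param path TSV path.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  ortholog_table(tab)
}

#' @rdname ortholog_table
#' @param table an `ortholog_table`.
#' @export
write_ortholog_table <- function(table, path) {
  stopifnot(inherits(table, "ortholog_table"))
  mouse <- rep(names(table), lengths(table))
  tab <- data.frame(mouse_symbol = mouse,
                    human_symbol = unlist(table, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map a mouse signature into human gene space
#'
#' Translates each mouse symbol through the ortholog table.  Unmapped
#' symbols are reported in `dropped` (lossiness is data, not an error: in
#' the motivating study only 94 human orthologs could be associated with a
#' 131-gene mouse signature).  One-to-many mappings resolve to the
#' lexicographically first human symbol unless `expand = TRUE`; many-to-one
#' collisions are deduplicated with a warning.  Per-gene directions, when
#' given, are carried through (on collision the first mapped gene wins).
#'
#' @param genes character vector of mouse symbols.
#' @param table an `ortholog_table`.
#' @param directions optional named +1/-1 vector keyed by mouse symbol.
#' @param expand expand one-to-many mappings to all human targets.
#' @return list with `human_genes`, `directions` (NULL if none supplied)
#'   and `dropped` (mouse symbols without an ortholog).
#' @export
map_signature <- function(genes, table, directions = NULL, expand = FALSE) {
  stopifnot(inherits(table, "ortholog_table"))
  genes <- as.character(genes)
  hits <- genes %in% names(table)
  dropped <- genes[!hits]
  human <- character(0)
  dir_out <- numeric(0)
  for (g in genes[hits]) {
    targets <- sort(table[[g]])
    if (!expand && length(targets) > 1L) {
      warning(sprintf("mouse gene %s maps to %d human symbols; using %s",
                      g, length(targets), targets[1L]), call. = FALSE)
      targets <- targets[1L]
    }
    for (h in targets) {
      if (h %in% human) {
        warning(sprintf("human symbol %s already mapped; deduplicated", h),
                call. = FALSE)
        next
      }
      human <- c(human, h)
      if (!is.null(directions)) {
        dir_out[h] <- unname(directions[g])
      }
    }
  }
  list(human_genes = human,
       directions = if (is.null(directions)) NULL else dir_out,
       dropped = dropped)
}
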