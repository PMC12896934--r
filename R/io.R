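#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `set_name`, `description`, then one or more member gene ids. Member lists
#' are deduplicated preserving first occurrence. Comment (`#`) and blank
#' lines are skipped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (one per set), with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  sets <- list()
  desc <- character()
  for (i in idx) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop_format("malformed GMT line %d in %s: need set name, description and >=1 member", i, path)
    }
    nm <- fields[1]
    members <- unique(fields[-(1:2)])
    if (!length(members)) stop_format("empty gene set '%s' at line %d in %s", nm, i, path)
    sets[[nm]] <- members
    desc[nm] <- fields[2]
  }
  if (!length(sets)) stop_format("no gene sets found in %s", path)
  attr(sets, "descriptions") <- desc
  sets
}

#' Read an undirected gene-interaction edge list
#'
#' Two whitespace/tab-separated gene ids per line. Self-loops are dropped
#' with a warning; duplicate edges (in either orientation) are collapsed to
#' a single undirected edge.
#'
#' @param path Edge-list file path. A header line `from to` (or any
#'   non-duplicated first line) is treated as data unless it starts with `#`.
#' @return data.frame with character columns `from`, `to` (lexicographically
#'   ordered within each row), one row per undirected edge.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: %s", path)
  lines <- drop_comment_blank(readLines(path, warn = FALSE))
  if (!length(lines)) stop_format("no edges found in %s", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop_format("malformed edge line (expected 2 fields): line %d in %s", bad[1], path)
  }
  from <- vapply(parts, `[`, "", 1)
  to <- vapply(parts, `[`, "", 2)
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  n_dup <- sum(!keep)
  if (n_dup) message(sprintf("collapsed %d duplicate edge(s)", n_dup))
  edges
}

#' Read a per-sample trait table
#'
#' TSV with columns `sample_id`, `group` and one numeric column per trait.
#'
#' @param path Trait-table path.
#' @return data.frame with `sample_id`, `group` and numeric trait columns.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: %s", path)
  tab <- utils::read.delim(path, comment.char = "#", blank.lines.skip = TRUE,
                           stringsAsFactors = FALSE)
  validate_trait_table(tab)
}

validate_trait_table <- function(tab) {
  need <- c("sample_id", "group")
  if (!all(need %in% names(tab))) {
    stop_format("trait table must have columns: %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(tab$group), GROUP_LEVELS)
  if (length(bad)) {
    stop_format("unknown group label(s) in trait table: %s", paste(bad, collapse = ", "))
  }
  traits <- setdiff(names(tab), need)
  for (tr in traits) {
    if (!is.numeric(tab[[tr]])) stop_format("trait column '%s' is not numeric", tr)
    if (any(is.infinite(tab[[tr]]))) stop_format("trait column '%s' has infinite values", tr)
  }
  tab
}

#' Read a two-column gene-length table
#'
#' @param path TSV with columns `gene_id` and `length` (bases).
#' @return Named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: %s", path)
  tab <- utils::read.delim(path, comment.char = "#", blank.lines.skip = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_format("gene length table needs two columns")
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}
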