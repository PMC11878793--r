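#' The functional-group definition table
#'
#' Loads the packaged table of 82 named SMARTS patterns (or a user-supplied
#' table in the same format: tab-separated `name` and `smarts` columns,
#' `#`-prefixed comment lines). Names must be unique and every SMARTS must
#' compile; the table is validated on first load and cached for the session.
#'
#' @param path Path to a table file; `NULL` uses the packaged 82-entry table.
#' @param validate Check that every SMARTS compiles (requires the RDKit
#'   helper). Default `TRUE`.
#' @return A tibble with columns `name` and `smarts` and a `hash` attribute
#'   identifying the table contents.
#' @export
fg_table <- function(path = NULL, validate = TRUE) {
  if (is.null(path)) {
    if (!is.null(the$fg_table)) {
      return(the$fg_table)
    }
    path <- system.file("extdata", "functional_groups.tsv", package = "fragprompt",
                        mustWork = TRUE)
    default <- TRUE
  } else {
    default <- FALSE
  }
  lines <- readLines(path, encoding = "UTF-8")
  # only whole comment lines are stripped: '#' is meaningful inside SMARTS
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("name", "smarts") %in% names(tab))) {
    abort("Functional-group table needs `name` and `smarts` columns.")
  }
  tab <- tibble::as_tibble(tab[c("name", "smarts")])
  if (anyDuplicated(tab$name)) abort("Functional-group names must be unique.")
  if (validate) {
    ok <- check_smarts(tab$smarts)
    if (!all(ok)) {
      bad <- tab$name[!ok]
      abort(c("Some SMARTS patterns do not compile:",
              setNames(bad, rep("x", length(bad)))))
    }
  }
  attr(tab, "hash") <- rlang::hash(list(tab$name, tab$smarts))
  if (default) the$fg_table <- tab
  tab
}

#' Detect functional groups in molecules
#'
#' Substructure-matches every table SMARTS against each molecule. Each
#' distinct match (a distinct atom set) becomes one row; multiple matches of
#' the same pattern each count. Ordering is deterministic: by table entry
#' index, then by sorted atom indices. Molecules with no matches yield zero
#' rows.
#'
#' @param molecules A character vector of SMILES, or a data frame with a
#'   `smiles` column.
#' @param table A [fg_table()].
#' @return A tibble with columns `smiles` (canonical), `input_smiles`,
#'   `match_id` (per-molecule running index), `group_id` (1-based table
#'   index), `fg_name` and `atoms` (list-column of 1-based atom indices).
#' @examples
#' \dontrun{
#' detect_functional_groups("CCO")
#' }
#' @export
detect_functional_groups <- function(molecules, table = fg_table()) {
  smiles <- if (is.data.frame(molecules)) molecules$smiles else molecules
  info <- mol_info(smiles, table = table)
  require_parsed(info, smiles)
  purrr::map2_dfr(info, smiles, function(rec, s) {
    m <- length(rec$fg$gid)
    tibble::tibble(
      smiles = rep(rec$canonical, m),
      input_smiles = rep(s, m),
      match_id = seq_len(m),
      group_id = rec$fg$gid,
      fg_name = table$name[rec$fg$gid],
      atoms = rec$fg$atoms
    )
  })
}
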