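# Bridge to the bundled RDKit helper. All chemistry (SMILES parsing, BRICS,
# SMARTS matching, descriptors) is computed in one batched subprocess call per
# cache miss; results are memoised for the session.

find_python <- function() {
  if (!is.null(the$python)) {
    return(the$python)
  }
  p <- Sys.getenv("FRAGPROMPT_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    abort("No python interpreter found on PATH; RDKit is required for chemistry support.")
  }
  the$python <- unname(p)
  the$python
}

helper_script <- function() {
  system.file("python", "mol_helper.py", package = "fragprompt", mustWork = TRUE)
}

call_mol_helper <- function(mode, request) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(
    find_python(), c(shQuote(helper_script()), mode, shQuote(infile), shQuote(outfile)),
    stdout = FALSE, stderr = FALSE
  ))
  if (!identical(status, 0L) || !file.exists(outfile)) {
    abort(sprintf("RDKit helper failed (mode '%s', exit status %s)", mode, status))
  }
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

mol_cache <- function() {
  if (is.null(the$mol_cache)) the$mol_cache <- new.env(parent = emptyenv())
  the$mol_cache
}

cache_key <- function(smiles, table_hash) paste0(table_hash, "\r", smiles)

# Fetch raw molecule records (atoms, bonds, BRICS fragments, descriptors,
# scaffold, functional-group matches) for a SMILES vector, batching misses.
mol_info <- function(smiles, table = fg_table()) {
  stopifnot(is.character(smiles))
  th <- attr(table, "hash")
  cache <- mol_cache()
  keys <- cache_key(smiles, th)
  miss <- !vapply(keys, exists, logical(1), envir = cache)
  if (any(miss)) {
    todo <- unique(smiles[miss])
    req <- list(
      smiles = as.list(todo),
      fg = purrr::map2(table$name, table$smarts, ~ list(name = .x, smarts = .y))
    )
    res <- call_mol_helper("mols", req)
    for (i in seq_along(todo)) {
      assign(cache_key(todo[i], th), simplify_mol_record(res$mols[[i]]), envir = cache)
    }
  }
  lapply(keys, get, envir = cache)
}

simplify_mol_record <- function(rec) {
  if (!isTRUE(rec$ok)) {
    return(list(ok = FALSE, input = rec$input, error = rec$error))
  }
  atoms <- lapply(rec$atoms, function(x) unlist(x) %||% character(0))
  bonds <- lapply(rec$bonds, function(x) unlist(x))
  if (is.null(bonds$a)) bonds <- list(a = integer(0), b = integer(0), type = character(0),
                                      conj = integer(0), ring = integer(0), stereo = character(0))
  list(
    ok = TRUE,
    input = rec$input,
    canonical = rec$canonical,
    scaffold = rec$scaffold %||% "",
    atoms = atoms,
    bonds = bonds,
    # 0-based atom indices from RDKit -> 1-based for R
    frags = lapply(rec$frags, function(f) unlist(f) + 1L),
    frag_edges = list(
      u = unlist(rec$frag_edges$u) %||% integer(0),
      v = unlist(rec$frag_edges$v) %||% integer(0),
      la = unlist(rec$frag_edges$la) %||% integer(0),
      lb = unlist(rec$frag_edges$lb) %||% integer(0)
    ),
    frag_desc = lapply(rec$frag_desc, function(d) {
      if (is.null(d)) return(NULL)
      list(maccs = unlist(d$maccs) %||% integer(0),
           elems = unlist(d$elems), tpsa = d$tpsa, heavy = d$heavy,
           rings = d$rings, hbd = d$hbd, hba = d$hba)
    }),
    fg = list(
      gid = unlist(rec$fg$gid) %||% integer(0),
      atoms = lapply(rec$fg$atoms %||% list(), function(a) unlist(a) + 1L)
    )
  )
}

require_parsed <- function(info, smiles) {
  bad <- !vapply(info, function(x) isTRUE(x$ok), logical(1))
  if (any(bad)) {
    abort(c("Unparseable or empty SMILES:",
            setNames(utils::head(smiles[bad], 5), rep("x", min(sum(bad), 5)))),
          class = "fragprompt_parse_error")
  }
  invisible(info)
}

check_smarts <- function(smarts) {
  res <- call_mol_helper("check_smarts", list(smarts = as.list(smarts)))
  vapply(res$ok, isTRUE, logical(1))
}
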