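#' Read a chemical-space definition file
#'
#' Plain key-value format, one atom type per line:
#' \preformatted{
#' # comment lines and blank lines are ignored
#' C: 4
#' H: 1
#' F: 1
#' natoms: [2, 8]
#' }
#' The same element label may appear with several valences (each line is
#' one atom type), which is why the file is parsed line-wise rather than
#' as a strict YAML mapping; the `natoms` value is YAML (`[min, max]`).
#'
#' @param path file path.
#' @return a [chemical_space()].
#' @export
read_space_config <- function(path) {
  if (!file.exists(path)) stop("space config not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  els <- character(0); vals <- integer(0); natoms <- NULL
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key == "natoms") {
      natoms <- unlist(yaml::yaml.load(val))
      if (length(natoms) != 2L) stop("natoms must be [min, max]")
    } else {
      v <- suppressWarnings(as.integer(val))
      if (is.na(v)) stop("bad valence for ", key, ": ", val)
      els <- c(els, key); vals <- c(vals, v)
    }
  }
  if (is.null(natoms)) stop("config is missing the natoms line")
  chemical_space(els, vals, natoms)
}

#' Write a chemical-space definition file
#' @param space a [chemical_space()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_space_config <- function(space, path) {
  stopifnot(inherits(space, "chemical_space"))
  lines <- c(sprintf("%s: %d", space$elements, space$valences),
             sprintf("natoms: [%d, %d]", space$natoms[1], space$natoms[2]))
  writeLines(lines, path)
  invisible(path)
}

#' Persist a counts database as CSV (+ calibration JSON sidecar)
#'
#' Append-only on disk: when the CSV already exists, existing keys win and
#' only new records are appended.  Calibration constants go to
#' `<path>.json`.
#' @param db a [counts_db()].
#' @param path CSV path.
#' @param cal optional [calibration_constants()] for the sidecar.
#' @return `path`, invisibly.
#' @export
write_counts_db <- function(db, path, cal = NULL) {
  stopifnot(inherits(db, "counts_db"))
  recs <- db$records
  recs$tool_version <- as.character(utils::packageVersion("rrspace"))
  if (file.exists(path)) {
    old <- utils::read.csv(path, stringsAsFactors = FALSE)
    recs <- rbind(old, recs[!(recs$key %in% old$key), , drop = FALSE])
  }
  utils::write.csv(recs, path, row.names = FALSE)
  if (!is.null(cal)) {
    jsonlite::write_json(unclass(cal), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load a counts database written by [write_counts_db()]
#' @param path CSV path.
#' @return list with `db` (a `counts_db`) and `cal` (calibration constants
#'   or NULL when no sidecar exists).
#' @export
read_counts_db <- function(path) {
  recs <- utils::read.csv(path, stringsAsFactors = FALSE)
  recs$tool_version <- NULL
  cal <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    obj <- jsonlite::read_json(side, simplifyVector = TRUE)
    cal <- calibration_constants(obj$a7, obj$b7, obj$a10, obj$b10)
  }
  list(db = counts_db(recs), cal = cal)
}

#' SMILES string of a sampled molecule
#'
#' Spanning-tree traversal with ring-closure digits; every atom is written
#' in brackets (including explicit `[H]`) and bond orders 2, 3, 4 map to
#' `=`, `#`, `$`.  Bond orders above 4 have no SMILES syntax — use
#' [proto_to_json()] or [write_sdf()] for those.
#' @param mol a `protomolecule` with `elements`, or a `molecule_sample`.
#' @return character scalar.
#' @export
write_smiles <- function(mol) {
  if (inherits(mol, "molecule_sample")) mol <- mol$protomolecule
  stopifnot(inherits(mol, "protomolecule"))
  if (is.null(mol$elements)) stop("molecule carries no element labels")
  if (any(mol$edges[, 3L] > 4L))
    stop("bond order above 4 is not expressible in SMILES; use JSON or SDF")
  n <- length(mol$degree)
  A <- adjacency_multiplicity(mol)
  bsym <- c("", "=", "#", "$")
  visited <- logical(n)
  ring_id <- 0L
  ring_at <- vector("list", n)  # per atom: list of c(digit, order)
  ring_open <- matrix(0L, 0L, 2L)
  # pre-pass: find back edges via DFS (non-tree edges of a connected
  # undirected DFS always join an ancestor-descendant pair)
  parent <- rep(NA_integer_, n)
  tree_children <- vector("list", n)
  back_edges <- NULL
  recorded <- new.env(parent = emptyenv())
  dfs <- function(v) {
    for (u in which(A[v, ] > 0L)) {
      if (!visited[u]) {
        visited[u] <<- TRUE
        parent[u] <<- v
        tree_children[[v]] <<- c(tree_children[[v]], u)
        dfs(u)
      } else if (u != parent[v]) {
        pk <- paste0(min(u, v), "_", max(u, v))
        if (is.null(recorded[[pk]])) {
          recorded[[pk]] <- TRUE
          back_edges <<- rbind(back_edges, c(u, v))
        }
      }
    }
  }
  visited[1L] <- TRUE
  parent[1L] <- 0L
  dfs(1L)
  if (!all(visited)) stop("molecule is not connected")
  if (!is.null(back_edges)) {
    for (r in seq_len(nrow(back_edges))) {
      ring_id <- ring_id + 1L
      u <- back_edges[r, 1L]; v <- back_edges[r, 2L]
      ring_at[[u]] <- c(ring_at[[u]], list(c(ring_id, A[u, v])))
      ring_at[[v]] <- c(ring_at[[v]], list(c(ring_id, A[u, v])))
    }
  }
  digit_str <- function(id) if (id < 10L) as.character(id) else sprintf("%%%d", id)
  emit <- function(v) {
    s <- paste0("[", mol$elements[v], "]")
    for (rb in ring_at[[v]]) {
      s <- paste0(s, bsym[rb[2L]], digit_str(rb[1L]))
    }
    for (u in tree_children[[v]]) {
      s <- paste0(s, "(", bsym[A[v, u]], emit(u), ")")
    }
    s
  }
  emit(1L)
}

#' Write molecules to a SMILES line file
#' @param mols list of molecules (see [write_smiles()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(mols, path) {
  writeLines(vapply(mols, write_smiles, character(1)), path)
  invisible(path)
}

#' Write molecules to an SDF (V2000) file
#'
#' Bond order equals edge multiplicity; orders above 3 are nonstandard in
#' V2000 but written numerically.
#' @param mols list of molecules.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    if (inherits(mol, "molecule_sample")) mol <- mol$protomolecule
    els <- if (!is.null(mol$elements)) mol$elements else sprintf("X%d", mol$type)
    n <- length(mol$degree); ne <- nrow(mol$edges)
    writeLines(c(sprintf("molecule_%d", k), "  rrspace", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, ne), con)
    for (i in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, els[i]), con)
    }
    for (r in seq_len(ne)) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                         mol$edges[r, 1L], mol$edges[r, 2L], mol$edges[r, 3L]), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read molecules from SMILES, SDF or graph-JSON files
#'
#' SMILES lines are converted to explicit-hydrogen SDF via OpenBabel
#' (packages ChemmineR/ChemmineOB, Suggests); each atom's valence is then
#' its realized degree (sum of bond orders).  Unparseable or disconnected
#' records are skipped and counted.
#'
#' @param path input file.
#' @param format `"smiles"`, `"sdf"` or `"json"`; default guessed from the
#'   extension.
#' @return list of `protomolecule`s with attribute `n_skipped`.
#' @export
read_molecules <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     smi = , smiles = "smiles",
                     sdf = , mol = "sdf",
                     json = "json",
                     stop("cannot guess format of ", path))
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(paste(readLines(path), collapse = ""),
                              simplifyVector = FALSE)
    if (!is.null(obj$vertices)) obj <- list(obj)
    mols <- lapply(obj, function(o)
      proto_from_json(jsonlite::toJSON(o, auto_unbox = TRUE)))
    attr(mols, "n_skipped") <- 0L
    return(mols)
  }
  if (format == "smiles") {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("SMILES input requires the ChemmineOB package")
    src <- paste0(paste(readLines(path), collapse = "\n"), "\n")
    sdf_txt <- ChemmineOB::convertFormat(
      "SMI", "SDF", source = src,
      options = data.frame(names = "h", args = ""))
    return(parse_sdf_text(strsplit(sdf_txt, "\n", fixed = TRUE)[[1L]]))
  }
  parse_sdf_text(readLines(path))
}

# minimal V2000 block parser (counts line, atom block, bond block)
parse_sdf_text <- function(lines) {
  mols <- list(); skipped <- 0L
  recs <- split(lines, cumsum(c(0L, utils::head(lines, -1L) == "$$$$")))
  for (rec in recs) {
    if (all(!nzchar(trimws(rec)))) next
    ok <- tryCatch({
      cl <- rec[4L]
      n <- as.integer(substr(cl, 1L, 3L)); ne <- as.integer(substr(cl, 4L, 6L))
      if (is.na(n) || n < 1L) stop("bad counts line")
      atoms <- rec[5:(4L + n)]
      els <- trimws(substr(atoms, 32L, 34L))
      edges <- matrix(0L, ne, 3L)
      if (ne > 0L) {
        bl <- rec[(5L + n):(4L + n + ne)]
        edges[, 1L] <- as.integer(substr(bl, 1L, 3L))
        edges[, 2L] <- as.integer(substr(bl, 4L, 6L))
        edges[, 3L] <- as.integer(substr(bl, 7L, 9L))
      }
      deg <- integer(n)
      for (r in seq_len(nrow(edges))) {
        deg[edges[r, 1L]] <- deg[edges[r, 1L]] + edges[r, 3L]
        deg[edges[r, 2L]] <- deg[edges[r, 2L]] + edges[r, 3L]
      }
      if (any(deg == 0L)) stop("atom with no bonds")
      mols[[length(mols) + 1L]] <- molecule_from_atoms(els, deg, edges)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) skipped <- skipped + 1L
  }
  if (skipped > 0L)
    message(skipped, " record(s) skipped while reading molecules")
  attr(mols, "n_skipped") <- skipped
  mols
}

# FNV-1a hash of a string: cheap deterministic config fingerprinting.
# 32-bit arithmetic carried in doubles (R integers overflow at 2^31):
# the xor only ever touches the low byte, and the multiply is split into
# 16-bit halves to stay within exact double precision.
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- ((h %/% 65536 * p) %% 65536) * 65536 + (h %% 65536) * p
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run manifest
#'
#' Reproducibility sidecar written next to CLI outputs: tool version, a
#' fingerprint of the space config, seeds, tier usage, timestamp.
#' @param space_config_text the config file contents (character vector).
#' @param seed integer seed used.
#' @param tiers named count of tier usage (optional).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(space_config_text, seed = NA_integer_, tiers = NULL) {
  structure(list(
    tool = "rrspace",
    version = as.character(utils::packageVersion("rrspace")),
    space_hash = fnv1a(paste(space_config_text, collapse = "\n")),
    seed = seed,
    tiers = as.list(tiers),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a run manifest as JSON next to an output file
#' @param manifest a [run_manifest()].
#' @param out_path the output file the manifest describes; the manifest
#'   goes to `<out_path>.manifest.json`.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(manifest, out_path) {
  p <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(unclass(manifest), p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}
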