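#' Read a C-alpha trace from a PDB file
#'
#' A fixed-width parser for PDB `ATOM`/`HETATM` records that extracts one
#' C-alpha per residue.  Only the first `MODEL` block is read by default;
#' alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties broken alphabetically by altloc code); selenomethionine
#' (`MSE`, a `HETATM`) is included as an ordinary residue by default.
#' Insertion-code residues are distinct residues, kept in file order.
#'
#' @param x a file path, or PDB text (a single string or a character vector
#'   of lines).
#' @param model which model of a multi-model file to read (default 1).
#' @param altloc `"occupancy"` (default: highest occupancy, ties to the
#'   alphabetically first code) or a single altloc letter to prefer
#'   explicitly (falling back to highest occupancy when absent).
#' @param include_mse include `HETATM` MSE records as residues (default
#'   TRUE).
#' @param structure_id identifier stored on the result; defaults to the file
#'   name.
#' @return An object of class `"structure_trace"`: list with
#'   `structure_id` and `chains`, each chain a list of `chain_id` and a
#'   data frame `residues` with columns `resseq`, `icode`, `resname`, `x`,
#'   `y`, `z`, `occupancy`, `bfactor`.
#' @export
read_calpha_trace <- function(x, model = 1L, altloc = "occupancy",
                              include_mse = TRUE, structure_id = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    if (is.null(structure_id))
      structure_id <- sub("\\.(pdb|ent)$", "", basename(x))
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1L]] else x
    if (is.null(structure_id)) structure_id <- "structure"
  }

  rec <- substr(lines, 1L, 6L)
  cur_model <- 0L
  in_wanted_model <- TRUE
  seen_model <- FALSE
  rows <- vector("list", length(lines))
  nr <- 0L
  for (ln in seq_along(lines)) {
    r <- rec[ln]
    if (r == "MODEL ") {
      seen_model <- TRUE
      cur_model <- cur_model + 1L
      in_wanted_model <- (cur_model == model)
      next
    }
    if (r == "ENDMDL") next
    if (!(r %in% c("ATOM  ", "HETATM"))) next
    if (seen_model && !in_wanted_model) next
    line <- lines[ln]
    name <- trimws(substr(line, 13L, 16L))
    if (name != "CA") next
    resname <- trimws(substr(line, 18L, 20L))
    if (r == "HETATM" && !(include_mse && resname == "MSE")) next
    if (resname == "CA") next   # calcium ion masquerading as CA atom name
    xyz <- suppressWarnings(as.numeric(c(substr(line, 31L, 38L),
                                         substr(line, 39L, 46L),
                                         substr(line, 47L, 54L))))
    resseq <- suppressWarnings(as.integer(substr(line, 23L, 26L)))
    if (anyNA(xyz) || is.na(resseq))
      stop(sprintf("parse error at line %d: malformed fixed-width ATOM record",
                   ln))
    occ <- suppressWarnings(as.numeric(substr(line, 55L, 60L)))
    bf <- suppressWarnings(as.numeric(substr(line, 61L, 66L)))
    nr <- nr + 1L
    rows[[nr]] <- data.frame(
      chain = substr(line, 22L, 22L),
      resseq = resseq,
      icode = trimws(substr(line, 27L, 27L)),
      resname = resname,
      altloc = substr(line, 17L, 17L),
      x = xyz[1L], y = xyz[2L], z = xyz[3L],
      occupancy = if (is.na(occ)) 1 else occ,
      bfactor = if (is.na(bf)) 0 else bf,
      stringsAsFactors = FALSE)
  }
  if (nr == 0L) stop("empty trace: no C-alpha atoms found")
  atoms <- do.call(rbind, rows[seq_len(nr)])

  # resolve altlocs per residue
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "\r")
  keep <- vapply(split(seq_len(nrow(atoms)), factor(key, unique(key))),
                 function(idx) {
    if (length(idx) == 1L) return(idx)
    a <- atoms[idx, ]
    if (altloc != "occupancy" && any(a$altloc == altloc))
      return(idx[a$altloc == altloc][1L])
    best <- which(a$occupancy == max(a$occupancy))
    idx[best[order(a$altloc[best])][1L]]
  }, integer(1))
  atoms <- atoms[sort(keep), , drop = FALSE]

  chains <- lapply(split(atoms, factor(atoms$chain, unique(atoms$chain))),
                   function(a) {
    rownames(a) <- NULL
    list(chain_id = a$chain[1L],
         residues = a[, c("resseq", "icode", "resname", "x", "y", "z",
                          "occupancy", "bfactor")])
  })
  names(chains) <- NULL
  structure(list(structure_id = structure_id, chains = chains),
            class = "structure_trace")
}

#' @export
print.structure_trace <- function(x, ...) {
  cat(sprintf("C-alpha trace '%s': %d chain%s\n", x$structure_id,
              length(x$chains), if (length(x$chains) == 1) "" else "s"))
  for (ch in x$chains)
    cat(sprintf("  chain %s: %d residues (%s-%s)\n", ch$chain_id,
                nrow(ch$residues), ch$residues$resseq[1L],
                ch$residues$resseq[nrow(ch$residues)]))
  invisible(x)
}

#' One-letter amino-acid sequence of a trace
#'
#' @param trace a [read_calpha_trace()] object.
#' @param chain chain id, or NULL for all chains concatenated in file order.
#' @return single character string; nonstandard residues map to `X`, MSE to
#'   `M`.
#' @export
trace_sequence <- function(trace, chain = NULL) {
  res <- trace_residues(trace, chain)
  paste(three_to_one(res$resname), collapse = "")
}

trace_residues <- function(trace, chain = NULL) {
  chs <- trace$chains
  if (!is.null(chain)) chs <- Filter(function(c) c$chain_id %in% chain, chs)
  do.call(rbind, lapply(chs, function(ch)
    cbind(chain = ch$chain_id, ch$residues, stringsAsFactors = FALSE)))
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M")

three_to_one <- function(resname) {
  out <- AA3TO1[resname]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Write per-residue values into the b-factor column of a PDB file
#'
#' Stores a per-residue descriptor (or any user-defined value) in the
#' temperature-factor field (columns 61-66) of every atom of the residue,
#' leaving every other byte of the file untouched.  This is the standard
#' mechanism for carrying per-residue scores into molecular viewers, which
#' can colour structures by b-factor.
#'
#' Values are formatted `%6.2f` and clamped to the representable range
#' [-99.99, 999.99].  Residues not present in `values` receive `sentinel`
#' (default 0).  Values referencing residues absent from the file produce a
#' warning and are skipped.
#'
#' @param pdb_text original PDB content (path, string or vector of lines).
#' @param values data frame with columns `chain`, `resseq`, optionally
#'   `icode`, and `value`.  A [describe_structure()] table can be passed
#'   directly together with `column`.
#' @param column when `values` is a geometry table, which descriptor column
#'   to store (e.g. `"curvature"`).
#' @param sentinel value written for residues with no (or undefined) value.
#' @return character vector of output PDB lines.
#' @export
write_bfactor_pdb <- function(pdb_text, values, column = NULL, sentinel = 0) {
  lines <- if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
               file.exists(pdb_text)) readLines(pdb_text, warn = FALSE)
           else if (length(pdb_text) == 1L)
             strsplit(pdb_text, "\n", fixed = TRUE)[[1L]]
           else pdb_text
  if (!is.null(column)) {
    values <- data.frame(chain = values$chain, resseq = values$resseq,
                         icode = if (!is.null(values$icode)) values$icode
                                 else "",
                         value = values[[column]], stringsAsFactors = FALSE)
  }
  if (is.null(values$icode)) values$icode <- rep("", nrow(values))
  vkey <- paste(values$chain, values$resseq, trimws(values$icode), sep = "\r")
  vmap <- values$value[!is.na(values$value)]
  names(vmap) <- vkey[!is.na(values$value)]

  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  seen <- character(0)
  for (ln in which(is_atom)) {
    line <- lines[ln]
    key <- paste(substr(line, 22L, 22L),
                 as.integer(substr(line, 23L, 26L)),
                 trimws(substr(line, 27L, 27L)), sep = "\r")
    val <- if (key %in% names(vmap)) vmap[[key]] else sentinel
    seen <- c(seen, key)
    field <- sprintf("%6.2f", min(999.99, max(-99.99, val)))
    if (nchar(line) < 66L)
      line <- formatC(line, width = -66L)
    substr(line, 61L, 66L) <- field
    lines[ln] <- line
  }
  missing <- setdiff(names(vmap), unique(seen))
  if (length(missing) > 0L)
    warning(sprintf("%d value(s) reference residues absent from the file; skipped",
                    length(missing)))
  lines
}
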