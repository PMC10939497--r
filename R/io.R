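#' Read the per-amino-acid hydrophobic strength table
#'
#' Loads a TSV with columns \code{residue} (one-letter code) and \code{eps}
#' (relative hydrophobic strength in (0,1)). The bundled default
#' (\code{hydropathy_1bpa_synthetic.tsv}) is a documented stand-in scale --
#' a min-max normalized Kyte-Doolittle hydropathy mapped into (0,1) with the
#' charged residues slightly increased -- shipped so the pipeline runs
#' without external inputs. Swap in a measured scale by pointing \code{path}
#' at your own file.
#'
#' @param path TSV file path; default is the bundled table.
#' @return named numeric vector over the 20 amino acids.
#' @export
read_hydropathy <- function(path = system.file("extdata",
                                               "hydropathy_1bpa_synthetic.tsv",
                                               package = "onebpa")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("residue", "eps") %in% names(tab)))
    stop("hydropathy table needs columns 'residue' and 'eps'")
  setNames(tab$eps, tab$residue)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet} returning plain
#' character vectors of one-letter codes.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Net charge per residue of a sequence
#'
#' NCPR = (number of K/R minus number of D/E) divided by the sequence length,
#' in elementary charge units per residue. Histidine counts as neutral.
#'
#' @param seq character scalar (one-letter codes) or vector of sequences,
#'   which are concatenated (e.g. the two chains of a homodimer).
#' @return NCPR in e per residue.
#' @export
#' @examples
#' ncpr_from_sequence("PRPRPR")  # +0.5
ncpr_from_sequence <- function(seq) {
  v <- strsplit(paste(seq, collapse = ""), "")[[1]]
  (sum(v %in% c("K", "R")) - sum(v %in% c("D", "E"))) / length(v)
}

# fixed-width PDB ATOM/SEQRES reader (no Calpha-capable PDB parser is
# available in the supported R stack, so this minimal reader is local)
.parse_pdb_lines <- function(lines) {
  atom <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) {
    first_end <- endmdl[1]
    keep <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
    atom <- lines[keep & seq_along(lines) < first_end]
  }
  sub_s <- function(x, a, b) trimws(substr(x, a, b))
  data.frame(
    name    = sub_s(atom, 13, 16),
    altloc  = substr(atom, 17, 17),
    resname = sub_s(atom, 18, 20),
    chain   = substr(atom, 22, 22),
    resseq  = as.integer(sub_s(atom, 23, 26)),
    x = as.numeric(sub_s(atom, 31, 38)),
    y = as.numeric(sub_s(atom, 39, 46)),
    z = as.numeric(sub_s(atom, 47, 54)),
    stringsAsFactors = FALSE)
}

.parse_seqres <- function(lines) {
  sr <- lines[startsWith(lines, "SEQRES")]
  if (!length(sr)) return(NULL)
  chain <- substr(sr, 12, 12)
  out <- list()
  for (ch in unique(chain)) {
    toks <- unlist(strsplit(trimws(substr(sr[chain == ch], 20, 70)), "\\s+"))
    toks <- toks[nzchar(toks)]
    bad <- setdiff(unique(toks), names(.AA3))
    if (length(bad)) stop("unknown residue code in SEQRES: ",
                          paste(bad, collapse = ", "))
    out[[ch]] <- unname(.AA3[toks])
  }
  out
}

#' Parse a PDB structure into a coarse-grained model skeleton
#'
#' Extracts one bead per residue at the Calpha position (model 1 only;
#' altloc "A" preferred), converting Angstrom to nm. Residues present in the
#' chain's sequence (from SEQRES or the \code{sequence} argument) but absent
#' from the coordinates -- chain breaks, unresolved termini -- are kept as
#' beads with NA positions and flagged unresolved for later disorder calling
#' and placement. Multi-chain structures are preserved in one model with
#' \code{chain_ids} (a homodimer is one molecule).
#'
#' Construct numbering is 1-based over the modeled sequence; ATOM resSeq is
#' interpreted on that numbering (renumber upstream if the deposited file
#' uses an offset).
#'
#' @param pdb_text character scalar or vector of PDB lines (or a file path
#'   via \code{file}).
#' @param chains chains to keep (default all, in order of appearance).
#' @param sequence optional named list/vector of full-length one-letter
#'   sequences per chain, used when SEQRES records are absent.
#' @param file optional path to read instead of \code{pdb_text}.
#' @param name molecule name.
#' @return a \code{cg_model} (positions and residue names only; call
#'   [mark_disordered()], [assign_bead_properties()],
#'   [build_elastic_network()] next).
#' @export
parse_structure <- function(pdb_text = NULL, chains = NULL, sequence = NULL,
                            file = NULL, name = "") {
  lines <- if (!is.null(file)) readLines(file) else
    unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n"))
  atoms <- .parse_pdb_lines(lines)
  seqres <- .parse_seqres(lines)
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("no Calpha atoms found in the input")
  # a residue with coordinates but no Calpha cannot be coarse-grained
  key_all <- unique(paste(atoms$chain, atoms$resseq))
  key_ca <- unique(paste(ca$chain, ca$resseq))
  no_ca <- setdiff(key_all, key_ca)
  if (length(no_ca))
    stop("missing Calpha for resolved residue(s): ",
         paste(no_ca, collapse = ", "))
  # altloc: prefer "A" or blank, drop duplicates
  ca <- ca[ca$altloc %in% c(" ", "", "A"), , drop = FALSE]
  ca <- ca[!duplicated(ca[c("chain", "resseq")]), , drop = FALSE]
  if (is.null(chains)) chains <- unique(ca$chain)
  res_names <- character(0); pos <- NULL; chain_ids <- character(0)
  resolved <- logical(0)
  for (ch in chains) {
    cc <- ca[ca$chain == ch, , drop = FALSE]
    if (!nrow(cc)) stop("no Calpha atoms for chain ", ch)
    cc <- cc[order(cc$resseq), , drop = FALSE]
    bad <- setdiff(unique(cc$resname), names(.AA3))
    if (length(bad)) stop("unknown residue code: ", paste(bad, collapse = ", "))
    full <- if (!is.null(seqres) && !is.null(seqres[[ch]])) seqres[[ch]]
            else if (!is.null(sequence) && !is.null(sequence[[ch]]))
              strsplit(sequence[[ch]], "")[[1]]
            else NULL
    if (is.null(full)) {
      lo <- min(cc$resseq); hi <- max(cc$resseq)
      nn <- hi - lo + 1L
      nm <- rep(NA_character_, nn)
      idx <- cc$resseq - lo + 1L
    } else {
      nn <- length(full)
      nm <- full
      if (any(cc$resseq < 1 | cc$resseq > nn))
        stop("ATOM resSeq outside the 1..", nn, " construct numbering for chain ", ch)
      idx <- cc$resseq
    }
    p <- matrix(NA_real_, nn, 3)
    p[idx, ] <- cbind(cc$x, cc$y, cc$z) / 10  # Angstrom -> nm
    nm[idx] <- unname(.AA3[cc$resname])
    if (anyNA(nm))
      stop("unresolved residues without sequence information in chain ", ch,
           "; supply SEQRES records or the 'sequence' argument")
    res_names <- c(res_names, nm)
    pos <- rbind(pos, p)
    chain_ids <- c(chain_ids, rep(ch, nn))
    res <- rep(FALSE, nn); res[idx] <- TRUE
    resolved <- c(resolved, res)
  }
  new_cg_model(res_names, pos, chain_ids, kind = "component",
               resolved = resolved, name = name)
}

#' Write a cg_model as PDB text
#'
#' One CA ATOM record per bead with coordinates converted to Angstrom;
#' intended for visualization and round-trip checks, not archival.
#'
#' @param model a \code{cg_model} with all positions defined.
#' @param file optional path; if NULL the lines are returned.
#' @return invisibly (or visibly when \code{file} is NULL) the PDB lines.
#' @export
write_pdb <- function(model, file = NULL) {
  if (anyNA(model$positions)) stop("model has unplaced residues")
  three <- setNames(names(.AA3), unname(.AA3))
  n <- n_beads(model)
  # construct numbering restarts per chain
  resseq <- stats::ave(seq_len(n), model$chain_ids, FUN = seq_along)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), three[model$residue_names], substr(model$chain_ids, 1, 1),
    resseq, model$positions[, 1] * 10, model$positions[, 2] * 10,
    model$positions[, 3] * 10)
  lines <- c(lines, "END")
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}

#' Save / load a cg_model as a flat JSON file
#'
#' Documented reproducibility format holding names, positions, charges,
#' hydrophobic strengths, flags and the bond table.
#'
#' @param model a \code{cg_model}.
#' @param path file path.
#' @return \code{read_cg_model} returns the \code{cg_model}.
#' @export
write_cg_model <- function(model, path) {
  out <- unclass(model)
  out$positions <- as.data.frame(model$positions)
  names(out$positions) <- c("x", "y", "z")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_cg_model
#' @export
read_cg_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- new_cg_model(raw$residue_names,
                    as.matrix(raw$positions[c("x", "y", "z")]),
                    raw$chain_ids, kind = raw$kind, resolved = raw$resolved,
                    name = if (is.null(raw$name)) "" else raw$name)
  m$charges <- as.numeric(raw$charges)
  m$hydro_strengths <- as.numeric(raw$hydro_strengths)
  m$aromatic_flags <- as.logical(raw$aromatic_flags)
  m$disorder_mask <- as.logical(raw$disorder_mask)
  if (length(raw$bonds) && NROW(raw$bonds))
    m$bonds <- data.frame(i = as.integer(raw$bonds$i),
                          j = as.integer(raw$bonds$j),
                          b0 = as.numeric(raw$bonds$b0),
                          type = as.character(raw$bonds$type))
  m
}

#' Read / write binding-site annotations
#'
#' Annotations are TSV tables with columns \code{partner} (the native binding
#' partner, e.g. "NLS-cargo", "RanGTP") and \code{residue_index} (1-based
#' over the modeled construct). An optional \code{mapping} (data.frame with
#' columns \code{from}, \code{to}) renumbers deposited full-length indices
#' into construct numbering.
#'
#' @param path TSV path.
#' @param mapping optional renumbering table.
#' @return data.frame with columns partner, residue_index.
#' @export
read_annotation <- function(path, mapping = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("partner", "residue_index") %in% names(tab)))
    stop("annotation needs columns 'partner' and 'residue_index'")
  if (!is.null(mapping)) {
    idx <- match(tab$residue_index, mapping$from)
    if (anyNA(idx)) stop("annotation index missing from the mapping table")
    tab$residue_index <- mapping$to[idx]
  }
  tab[c("partner", "residue_index")]
}

#' @rdname read_annotation
#' @param annotation data.frame with partner, residue_index.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a trajectory in the portable text format
#'
#' The portable fallback trajectory format: a JSON header (box, times,
#' energies, config) plus a TSV of frames in long form (frame, bead, x, y,
#' z). Plain text, diff-able, and readable anywhere; no binary format is
#' bundled.
#'
#' @param traj a \code{cg_trajectory} from [run_langevin()].
#' @param path base path; \code{<path>.json} and \code{<path>.tsv} are
#'   written.
#' @return \code{read_trajectory} returns the \code{cg_trajectory}.
#' @export
write_trajectory <- function(traj, path) {
  hdr <- list(box = traj$box, times = traj$times, pe = traj$pe, ke = traj$ke,
              config = unclass(traj$config), n_beads = dim(traj$frames)[1])
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  d <- dim(traj$frames)
  long <- data.frame(
    frame = rep(seq_len(d[3]), each = d[1]),
    bead = rep(seq_len(d[1]), d[3]),
    x = as.vector(traj$frames[, 1, ]),
    y = as.vector(traj$frames[, 2, ]),
    z = as.vector(traj$frames[, 3, ]))
  write.table(long, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- read.delim(paste0(path, ".tsv"))
  n <- hdr$n_beads
  f <- max(long$frame)
  frames <- array(NA_real_, c(n, 3, f))
  frames[, 1, ] <- long$x
  frames[, 2, ] <- long$y
  frames[, 3, ] <- long$z
  structure(list(frames = frames, times = hdr$times, box = hdr$box,
                 pe = hdr$pe, ke = hdr$ke, config = hdr$config),
            class = "cg_trajectory")
}
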