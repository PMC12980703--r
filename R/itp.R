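# GROMACS-dialect .itp fragment parsing and surgical rewriting.
#
# Accepted grammar (the martinize2-style dialects):
#   * Go networks: an [ atomtypes ] section declaring virtual-site bead types
#     whose names END in an integer giving the 1-based bead index (e.g.
#     "mol_go_4"), plus a [ nonbond_params ] section with lines
#         <type_i> <type_j> <funct> <sigma nm> <epsilon kJ/mol>
#   * Elastic networks: a [ bonds ] section with lines
#         <i> <j> <funct> <r0 nm> <kappa kJ/mol/nm^2>
#     (1-based bead indices, funct 1).
# If [ nonbond_params ] is present the file is read as a Go network, otherwise
# a [ bonds ] section is required.  Comments (";") and unrecognized sections
# are retained verbatim and round-trip byte-identically.  When a numeric field
# must change, it is re-emitted as "%.8f" right-aligned to the original column
# width (the line widens only if the new number needs more characters).

tokenize_line <- function(line) {
  code <- sub(";.*$", "", line)
  m <- gregexpr("[^[:space:]]+", code)[[1]]
  if (m[1] == -1) return(NULL)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  list(tokens = substring(code, starts, starts + lens - 1),
       start = starts, stop = starts + lens - 1)
}

section_name <- function(line) {
  m <- regmatches(line, regexec("^[[:space:]]*\\[[[:space:]]*([A-Za-z_]+)[[:space:]]*\\]", line))[[1]]
  if (length(m) == 2) tolower(m[2]) else NA_character_
}

bead_index_from_type <- function(name) {
  m <- regmatches(name, regexec("([0-9]+)$", name))[[1]]
  if (length(m) < 2) return(NA_integer_)
  as.integer(m[2])
}

#' Read an interaction network from a GROMACS .itp fragment
#'
#' Parses the Go (`[ nonbond_params ]` + `[ atomtypes ]`) or elastic
#' (`[ bonds ]`) dialect described in the package's topology-format notes and
#' retains the full document so that [write_itp()] can round-trip unmodified
#' content byte-identically.
#'
#' @param path path to the .itp file.
#' @return a list with `network` (an `InteractionNetwork`) and `document`
#'   (opaque; pass to [write_itp()]).
#' @export
read_itp <- function(path) {
  .chk(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  section <- NA_character_
  seen <- character(0)
  recs <- list()
  for (ln in seq_along(lines)) {
    sec <- section_name(lines[ln])
    if (!is.na(sec)) { section <- sec; seen <- union(seen, sec); next }
    if (is.na(section)) next
    tk <- tokenize_line(lines[ln])
    if (is.null(tk)) next
    if (section == "nonbond_params") {
      .chk(length(tk$tokens) >= 5,
           "malformed [ nonbond_params ] line ", ln, ": need 5 fields")
      bi <- bead_index_from_type(tk$tokens[1])
      bj <- bead_index_from_type(tk$tokens[2])
      .chk(!is.na(bi) && !is.na(bj),
           "atom-type names on line ", ln, " do not end in a bead index")
      sigma <- suppressWarnings(as.numeric(tk$tokens[4]))
      eps <- suppressWarnings(as.numeric(tk$tokens[5]))
      .chk(is.finite(sigma) && is.finite(eps),
           "malformed numeric fields on line ", ln)
      recs[[length(recs) + 1]] <- list(kind = "go_lj", line = ln,
                                       i = bi - 1L, j = bj - 1L,
                                       strength = eps, geometry = sigma,
                                       geom_tok = 4L, str_tok = 5L, tk = tk)
    } else if (section == "bonds") {
      .chk(length(tk$tokens) >= 5,
           "malformed [ bonds ] line ", ln, ": need 5 fields")
      bi <- suppressWarnings(as.integer(tk$tokens[1]))
      bj <- suppressWarnings(as.integer(tk$tokens[2]))
      r0 <- suppressWarnings(as.numeric(tk$tokens[4]))
      k <- suppressWarnings(as.numeric(tk$tokens[5]))
      .chk(!is.na(bi) && !is.na(bj) && is.finite(r0) && is.finite(k),
           "malformed numeric fields on line ", ln)
      recs[[length(recs) + 1]] <- list(kind = "enm_harmonic", line = ln,
                                       i = bi - 1L, j = bj - 1L,
                                       strength = k, geometry = r0,
                                       geom_tok = 4L, str_tok = 5L, tk = tk)
    }
  }
  kinds <- vapply(recs, `[[`, character(1), "kind")
  use <- if ("nonbond_params" %in% seen && any(kinds == "go_lj")) "go_lj"
  else if ("bonds" %in% seen && any(kinds == "enm_harmonic")) "enm_harmonic"
  else stop("no [ nonbond_params ] or [ bonds ] section with entries found",
            call. = FALSE)
  recs <- recs[kinds == use]
  i <- vapply(recs, `[[`, integer(1), "i")
  j <- vapply(recs, `[[`, integer(1), "j")
  key <- paste(pmin(i, j), pmax(i, j))
  .chk(!anyDuplicated(key), "duplicate pair entries in .itp")
  strength <- vapply(recs, `[[`, numeric(1), "strength")
  geometry <- vapply(recs, `[[`, numeric(1), "geometry")
  network <- interaction_network(i, j, use, strength, geometry,
                                 n_beads = max(i, j) + 1L)
  document <- structure(list(lines = lines, records = recs, kind = use,
                             keys = key),
                        class = "ItpDocument")
  list(network = network, document = document)
}

replace_token <- function(line, start, stop, value) {
  width <- stop - start + 1L
  new <- sprintf("%.8f", value)
  new <- formatC(new, width = width)
  paste0(substr(line, 1, start - 1), new,
         substring(line, stop + 1))
}

#' Write a network back into its source .itp document
#'
#' Only strength (epsilon / kappa) and geometry (sigma / r0) fields whose
#' values actually changed are rewritten; every other byte of the document is
#' emitted verbatim, so writing an unchanged network reproduces the input file
#' exactly.
#'
#' @param document the `document` returned by [read_itp()].
#' @param network an `InteractionNetwork` whose contact pairs all occur in the
#'   document (error on any extra pair).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_itp <- function(document, network, path) {
  .chk(inherits(document, "ItpDocument"), "not an ItpDocument")
  .chk(network$kind == document$kind, "network kind does not match document")
  lines <- document$lines
  keymap <- setNames(seq_along(document$keys), document$keys)
  for (k in seq_len(n_contacts(network))) {
    key <- paste(network$contacts$i[k], network$contacts$j[k])
    rk <- keymap[key]
    .chk(!is.na(rk), "network pair (", key, ") absent from document")
    rec <- document$records[[rk]]
    new_s <- network$contacts$strength[k]
    new_g <- network$contacts$geometry[k]
    if (new_s == rec$strength && new_g == rec$geometry) next
    line <- lines[rec$line]
    # right-to-left so earlier token spans stay valid
    for (fld in list(c(rec$str_tok, new_s), c(rec$geom_tok, new_g))) {
      ti <- fld[1]
      line <- replace_token(line, rec$tk$start[ti], rec$tk$stop[ti], fld[2])
    }
    lines[rec$line] <- line
  }
  writeLines(lines, path)
  invisible(path)
}
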