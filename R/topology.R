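#' Declarative quadruplex-duplex hybrid (QDH) topology
#'
#' A `qdh_topology` is a declarative description of a QDH fold: the DNA
#' sequence, which residues assemble into G-tetrads or a G.C.G.C tetrad,
#' which form Watson-Crick G.C pairs, the glycosidic (syn/anti) states, the
#' loops and the groove-width annotations. It carries no coordinates; it is
#' the input from which hydrogen-bond, dihedral and planarity restraints are
#' generated and from which idealized reference coordinates can be built.
#'
#' Tetrad member order is meaningful: for a G-tetrad it encodes the cyclic
#' Hoogsteen donor-to-acceptor direction (residue i donates its H1/H21 to
#' residue i+1, cyclically); for a G.C.G.C tetrad it lists the two
#' Watson-Crick pairs in base-pair order (G, C, G, C).
#'
#' @param name Short identifier for the fold.
#' @param sequence DNA sequence (characters A/C/G/T), 1-based residue
#'   numbering along this string.
#' @param tetrads List of tetrad specifications, ordered from the 5' stack
#'   to the 3' stack. Each element is a list with fields `members` (integer
#'   vector of 4 residue indices), `kind` (`"G"` or `"GCGC"`), `direction`
#'   (`"clockwise"`, `"anticlockwise"` or `"unspecified"`) and, for
#'   G.C.G.C tetrads, `slipped` (logical).
#' @param pairs Data frame with columns `g`, `c` (residue indices of the
#'   guanine and cytosine) and `role` (`"stem"` or `"junction"`); junction
#'   pairs are the Watson-Crick pairs that are simultaneously members of a
#'   G.C.G.C tetrad.
#' @param syn Integer vector of residues in the syn glycosidic state; all
#'   other residues are taken as anti.
#' @param loops List of loop annotations, each a list with `kind`
#'   (`"propeller"`, `"lateral"` or `"stem-loop"`), `from` and `to`
#'   (inclusive residue range).
#' @param grooves Character vector of groove-width labels
#'   (`"wide"`/`"medium"`/`"narrow"`), stored as annotation only.
#' @return An object of class `qdh_topology`.
#' @seealso [form1_topology()], [form2_topology()], [validate_topology()],
#'   [imino_census()]
#' @export
qdh_topology <- function(name, sequence, tetrads = list(),
                         pairs = data.frame(g = integer(), c = integer(),
                                            role = character()),
                         syn = integer(), loops = list(),
                         grooves = character()) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  tetrads <- lapply(tetrads, function(t) {
    t$members <- as.integer(t$members)
    if (is.null(t$kind)) t$kind <- "G"
    if (is.null(t$direction)) t$direction <- "unspecified"
    if (is.null(t$slipped)) t$slipped <- FALSE
    t
  })
  pairs <- data.frame(g = as.integer(pairs$g), c = as.integer(pairs$c),
                      role = as.character(pairs$role))
  syn <- sort(unique(as.integer(syn)))
  residues <- data.frame(
    index = seq_along(bases),
    base = bases,
    glycosidic = ifelse(seq_along(bases) %in% syn, "syn", "anti"),
    stringsAsFactors = FALSE
  )
  structure(
    list(name = name, sequence = sequence, residues = residues,
         tetrads = tetrads, pairs = pairs, syn = syn, loops = loops,
         grooves = grooves),
    class = "qdh_topology"
  )
}

#' @export
print.qdh_topology <- function(x, ...) {
  cat(sprintf("QDH topology '%s' (%d nt)\n", x$name, nchar(x$sequence)))
  cat(" ", x$sequence, "\n")
  for (t in x$tetrads) {
    lab <- paste0(x$residues$base[t$members], t$members, collapse = ".")
    cat(sprintf("  tetrad [%s] %s (%s)\n", t$kind, lab, t$direction))
  }
  if (nrow(x$pairs))
    cat(sprintf("  pairs: %s\n",
                paste0("G", x$pairs$g, ".C", x$pairs$c, collapse = ", ")))
  if (length(x$syn))
    cat(sprintf("  syn: %s\n", paste0(x$residues$base[x$syn], x$syn,
                                      collapse = ", ")))
  invisible(x)
}

#' Built-in PIM1 Form 1 QDH topology
#'
#' The (3+1) quadruplex-duplex hybrid adopted by the 27-nt construct
#' GCGGGAGGGCGCGCCAGCGGGGTCGGG: three stacked G-tetrads
#' (G3.G25.G22.G7, G4.G8.G21.G26, G5.G9.G20.G27, hydrogen-bond
#' directionality anticlockwise / clockwise / clockwise), a three-base-pair
#' Watson-Crick stem (G19.C10, G11.C18, G17.C12) capped by the hairpin loop
#' G13-C14-C15-A16 and stacked coaxially under the core, a single-residue
#' propeller loop (A6), a two-residue lateral loop (T23-C24), and syn
#' guanines G1, G3, G7, G20, G21 and G25.
#'
#' @return A [qdh_topology()] object.
#' @export
form1_topology <- function() {
  qdh_topology(
    name = "PIM1-Form1",
    sequence = "GCGGGAGGGCGCGCCAGCGGGGTCGGG",
    tetrads = list(
      list(members = c(3L, 25L, 22L, 7L), kind = "G",
           direction = "anticlockwise"),
      list(members = c(4L, 8L, 21L, 26L), kind = "G",
           direction = "clockwise"),
      list(members = c(5L, 9L, 20L, 27L), kind = "G",
           direction = "clockwise")
    ),
    pairs = data.frame(g = c(19L, 11L, 17L), c = c(10L, 18L, 12L),
                       role = "stem"),
    syn = c(1L, 3L, 7L, 20L, 21L, 25L),
    loops = list(
      list(kind = "propeller", from = 6L, to = 6L),
      list(kind = "lateral", from = 23L, to = 24L),
      list(kind = "stem-loop", from = 13L, to = 16L)
    ),
    grooves = c("wide", "medium", "medium", "narrow")
  )
}

#' Built-in PIM1 Form 2 QDH topology
#'
#' The chair-type quadruplex-duplex hybrid adopted by the 26-nt construct
#' GGGAGGGCGCGCCAGCGGGGTCGGGC: two G-tetrads (G2.G7.G18.G25 and
#' G3.G24.G19.G6) in an antiparallel up-down-up-down core, a slipped
#' G.C.G.C tetrad formed by the two junction Watson-Crick pairs G1.C26 and
#' G17.C8, a two-base-pair stem (G9.C16, G15.C10) capped by the hairpin
#' loop G11-C12-C13-A14, lateral loops A4-G5 and G20-T21-C22-G23, and syn
#' guanines G2, G6, G18 and G24.
#'
#' @return A [qdh_topology()] object.
#' @export
form2_topology <- function() {
  qdh_topology(
    name = "PIM1-Form2",
    sequence = "GGGAGGGCGCGCCAGCGGGGTCGGGC",
    tetrads = list(
      list(members = c(2L, 7L, 18L, 25L), kind = "G",
           direction = "unspecified"),
      list(members = c(3L, 24L, 19L, 6L), kind = "G",
           direction = "unspecified"),
      list(members = c(1L, 26L, 17L, 8L), kind = "GCGC",
           direction = "unspecified", slipped = TRUE)
    ),
    pairs = data.frame(g = c(1L, 17L, 9L, 15L), c = c(26L, 8L, 16L, 10L),
                       role = c("junction", "junction", "stem", "stem")),
    syn = c(2L, 6L, 18L, 24L),
    loops = list(
      list(kind = "lateral", from = 4L, to = 5L),
      list(kind = "lateral", from = 20L, to = 23L),
      list(kind = "stem-loop", from = 11L, to = 14L)
    ),
    grooves = c("wide", "narrow", "wide", "narrow")
  )
}

#' Validate a QDH topology
#'
#' Checks every structural invariant of the topology model and returns one
#' diagnostic message per violation (an empty character vector means the
#' topology is valid). Nothing is raised: callers that require validity
#' should test for an empty return.
#'
#' Checked rules: all residue indices lie within the sequence; tetrads have
#' exactly four members; G-tetrad members are all guanine; G.C.G.C-tetrad
#' members alternate G, C, G, C; pair guanines/cytosines match the
#' sequence; no residue belongs to two tetrads; no residue is in both a
#' tetrad and a pair except G.C.G.C members listed as junction pairs; loop
#' ranges are within the sequence.
#'
#' @param t A [qdh_topology()] object.
#' @return Character vector of diagnostics (empty if valid).
#' @export
validate_topology <- function(t) {
  msgs <- character()
  n <- nchar(t$sequence)
  bases <- t$residues$base
  bad <- !bases %in% c("A", "C", "G", "T")
  if (any(bad))
    msgs <- c(msgs, sprintf("sequence contains non-ACGT base at position %s",
                            paste(which(bad), collapse = ", ")))
  seen <- integer()
  for (i in seq_along(t$tetrads)) {
    tet <- t$tetrads[[i]]
    m <- tet$members
    if (length(m) != 4L) {
      msgs <- c(msgs, sprintf("tetrad %d does not have 4 members", i))
      next
    }
    if (any(m < 1L | m > n)) {
      msgs <- c(msgs, sprintf("tetrad %d has out-of-range member index", i))
      next
    }
    if (tet$kind == "G") {
      nonG <- m[bases[m] != "G"]
      if (length(nonG))
        msgs <- c(msgs, sprintf(
          "tetrad %d: non-G member%s %s in a G-tetrad", i,
          if (length(nonG) > 1) "s" else "",
          paste0(bases[nonG], nonG, collapse = ", ")))
    } else if (tet$kind == "GCGC") {
      if (!identical(bases[m], c("G", "C", "G", "C")))
        msgs <- c(msgs, sprintf(
          "tetrad %d: GCGC tetrad members must alternate G,C,G,C (got %s)",
          i, paste0(bases[m], m, collapse = ",")))
    } else {
      msgs <- c(msgs, sprintf("tetrad %d: unknown kind '%s'", i, tet$kind))
    }
    dup <- intersect(m, seen)
    if (length(dup))
      msgs <- c(msgs, sprintf("residue %s belongs to more than one tetrad",
                              paste0(bases[dup], dup, collapse = ", ")))
    seen <- c(seen, m)
  }
  gcgc_members <- unlist(lapply(t$tetrads,
                                function(x) if (x$kind == "GCGC") x$members))
  if (nrow(t$pairs)) {
    for (k in seq_len(nrow(t$pairs))) {
      g <- t$pairs$g[k]; cc <- t$pairs$c[k]
      if (g < 1L || g > n || cc < 1L || cc > n) {
        msgs <- c(msgs, sprintf("pair %d has out-of-range residue index", k))
        next
      }
      if (bases[g] != "G")
        msgs <- c(msgs, sprintf("pair %d: residue %d is %s, expected G",
                                k, g, bases[g]))
      if (bases[cc] != "C")
        msgs <- c(msgs, sprintf("pair %d: residue %d is %s, expected C",
                                k, cc, bases[cc]))
      for (r in c(g, cc)) {
        if (r %in% seen && !(r %in% gcgc_members &&
                             t$pairs$role[k] == "junction"))
          msgs <- c(msgs, sprintf(
            "residue %s%d is in both a tetrad and a non-junction pair",
            bases[r], r))
      }
    }
    dupp <- duplicated(c(t$pairs$g, t$pairs$c))
    if (any(dupp))
      msgs <- c(msgs, "a residue appears in more than one base pair")
  }
  if (any(t$syn < 1L | t$syn > n))
    msgs <- c(msgs, "syn list contains out-of-range residue index")
  for (lp in t$loops) {
    if (lp$from < 1L || lp$to > n || lp$from > lp$to)
      msgs <- c(msgs, sprintf("loop %s %d-%d has an invalid range",
                              lp$kind, lp$from, lp$to))
  }
  msgs
}

#' Imino-proton census of a QDH topology
#'
#' Counts the slow-exchanging guanine imino protons the fold is expected to
#' display in a 1D spectrum: one per guanine in a G-tetrad (the 10.8-12 ppm
#' region) and one per Watson-Crick G.C pair (the 12.7-14 ppm region).
#' Guanines of a G.C.G.C tetrad are hydrogen-bonded within Watson-Crick
#' pairs, so they are counted in the Watson-Crick tally, not the G-tetrad
#' tally. The built-in folds give (12, 3) for Form 1 and (8, 4) for Form 2.
#'
#' @param t A valid [qdh_topology()].
#' @return Named integer vector with elements `tetrad_G` and `wc`.
#' @export
imino_census <- function(t) {
  msgs <- validate_topology(t)
  if (length(msgs))
    stop("invalid topology: ", paste(msgs, collapse = "; "))
  gt <- unique(unlist(lapply(t$tetrads,
                             function(x) if (x$kind == "G") x$members)))
  c(tetrad_G = length(gt), wc = nrow(t$pairs))
}

#' Read / write a topology schema file
#'
#' Topologies are stored one per file in a flat YAML document with fields
#' `name`, `sequence`, `tetrads` (ordered member lists with kind,
#' direction and slipped flag), `pairs`, `syn`, `loops` and `grooves`.
#' Fixture files for the two built-in PIM1 folds ship under
#' `inst/extdata/form1.yaml` and `inst/extdata/form2.yaml`.
#'
#' @param t A [qdh_topology()].
#' @param path File path.
#' @return `read_topology()` returns a [qdh_topology()];
#'   `write_topology()` returns `path` invisibly.
#' @export
write_topology <- function(t, path) {
  doc <- list(
    name = t$name,
    sequence = t$sequence,
    tetrads = lapply(t$tetrads, function(x)
      list(members = as.integer(x$members), kind = x$kind,
           direction = x$direction, slipped = x$slipped)),
    pairs = lapply(seq_len(nrow(t$pairs)), function(k)
      list(g = t$pairs$g[k], c = t$pairs$c[k], role = t$pairs$role[k])),
    syn = as.integer(t$syn),
    loops = lapply(t$loops, function(x)
      list(kind = x$kind, from = as.integer(x$from), to = as.integer(x$to))),
    grooves = as.list(t$grooves)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  doc <- yaml::read_yaml(path)
  pairs <- if (length(doc$pairs)) {
    data.frame(g = vapply(doc$pairs, function(p) as.integer(p$g), 1L),
               c = vapply(doc$pairs, function(p) as.integer(p$c), 1L),
               role = vapply(doc$pairs, function(p) as.character(p$role), ""))
  } else data.frame(g = integer(), c = integer(), role = character())
  qdh_topology(
    name = doc$name, sequence = doc$sequence,
    tetrads = doc$tetrads, pairs = pairs,
    syn = unlist(doc$syn),
    loops = lapply(doc$loops, function(x)
      list(kind = x$kind, from = as.integer(x$from), to = as.integer(x$to))),
    grooves = unlist(doc$grooves)
  )
}
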