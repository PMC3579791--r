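#' Parse a Newick string into a rooted tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Internal node labels are
#' interpreted as clade support values when numeric (the usual output dialect
#' of ML bootstrap programs); the comment dialect `)[95]` is also accepted and
#' converted to node labels before parsing. Polytomies are allowed.
#'
#' @param text a single Newick string (must end in `;`).
#' @return an object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  # support-in-comment dialect: move ")[95]" into a node label
  text <- gsub("\\)\\s*\\[&?([0-9.]+)\\]", ")\\1", text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick: ", n_open, " '(' vs ",
         n_close, " ')'")
  }
  if (!grepl(";\\s*$", text)) stop("Newick string must end with ';'")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("Newick parse error: unreadable string")
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate taxon labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (!is.null(tree$edge.length)) {
    # ape encodes absent lengths in a mixed-length string as NaN; keep them
    neg <- !is.na(tree$edge.length) & tree$edge.length < 0
    if (any(neg)) {
      stop("negative branch length(s): ",
           paste(signif(tree$edge.length[neg], 4), collapse = ", "))
    }
    if (all(is.nan(tree$edge.length))) tree$edge.length <- NULL
  }
  tree
}

#' Write a tree to a Newick string
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

# leaf-set bitmask for every node, in a fixed taxon ordering ------------------

#' Node cluster masks
#'
#' For each node of a rooted tree, the set of descendant tips encoded as a
#' double-precision bitmask over `taxa` (safe for up to 52 taxa).
#'
#' @param tree a `phylo` object.
#' @param taxa reference taxon ordering; defaults to the tree's tips.
#' @return numeric vector of length `Nnode + Ntip`, indexed by node id.
#' @keywords internal
node_masks <- function(tree, taxa = tree$tip.label) {
  ntip <- length(tree$tip.label)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) stop("tree has tips absent from the reference taxon set: ",
                       paste(tree$tip.label[is.na(idx)], collapse = ", "))
  masks <- numeric(ntip + tree$Nnode)
  masks[seq_len(ntip)] <- 2^(idx - 1)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; c <- edge[i, 2]
    masks[p] <- masks[p] + masks[c]
  }
  masks
}

mask_of <- function(clade, taxa) {
  idx <- match(clade, taxa)
  if (anyNA(idx)) stop("clade taxa absent from reference set: ",
                       paste(clade[is.na(idx)], collapse = ", "))
  sum(2^(idx - 1))
}

#' Does a rooted tree contain a clade?
#'
#' TRUE iff some edge of the rooted tree subtends exactly the given taxa.
#'
#' @param tree a rooted `phylo` object.
#' @param clade character vector of taxon labels (a non-empty proper subset of
#'   the tree's tips).
#' @return logical.
#' @export
contains_clade <- function(tree, clade) {
  clade <- unique(trimws(clade))
  if (length(clade) == 0) stop("empty clade")
  missing <- setdiff(clade, tree$tip.label)
  if (length(missing)) stop("clade taxa missing from tree: ",
                            paste(missing, collapse = ", "))
  if (length(clade) >= length(tree$tip.label)) {
    stop("clade must be a proper subset of the tree's taxa")
  }
  if (length(clade) == 1) return(TRUE)
  target <- mask_of(clade, tree$tip.label)
  any(node_masks(tree) == target)
}

#' Collapse weakly supported branches into polytomies
#'
#' Contracts every internal (non-root) edge whose support value is below
#' `threshold`. Support values are taken from `tree$node.label`. The length of
#' a contracted edge is discarded (the operation is intended for
#' topology-level consumers such as MDC).
#'
#' @param tree a rooted `phylo` with numeric internal node labels.
#' @param threshold support threshold in percent; default 50.
#' @param missing_support one of `"error"` (default) or `"resolved"`; how to
#'   treat internal edges carrying no support value.
#' @return a `phylo`, possibly multifurcating; leaf set unchanged.
#' @export
collapse_low_support <- function(tree, threshold = 50,
                                 missing_support = c("error", "resolved")) {
  missing_support <- match.arg(missing_support)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (is.null(tree$node.label)) {
    supp <- rep(NA_real_, tree$Nnode)
  } else {
    supp <- suppressWarnings(as.numeric(tree$node.label))
  }
  internal_nodes <- setdiff(unique(tree$edge[, 1]), root)
  node_supp <- supp[internal_nodes - ntip]
  if (anyNA(node_supp) && missing_support == "error") {
    stop("missing support on ", sum(is.na(node_supp)),
         " internal edge(s); set missing_support = \"resolved\" to keep them")
  }
  drop_nodes <- internal_nodes[!is.na(node_supp) & node_supp < threshold]
  if (!length(drop_nodes)) return(tree)
  # contract each marked node into its parent
  edge <- tree$edge
  keep <- rep(TRUE, nrow(edge))
  parent_of <- integer(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  resolve <- function(p) { while (p %in% drop_nodes) p <- parent_of[p]; p }
  for (i in seq_len(nrow(edge))) {
    if (edge[i, 2] %in% drop_nodes) keep[i] <- FALSE
    else edge[i, 1] <- resolve(edge[i, 1])
  }
  edge <- edge[keep, , drop = FALSE]
  el <- if (!is.null(tree$edge.length)) tree$edge.length[keep] else NULL
  # renumber internal nodes consecutively
  kept_internal <- sort(unique(edge[, 1]))
  new_id <- integer(max(edge))
  new_id[seq_len(ntip)] <- seq_len(ntip)
  new_id[kept_internal] <- ntip + seq_along(kept_internal)
  edge[, 1] <- new_id[edge[, 1]]
  tip_rows <- edge[, 2] <= ntip
  edge[!tip_rows, 2] <- new_id[edge[!tip_rows, 2]]
  out <- list(edge = edge, tip.label = tree$tip.label,
              Nnode = length(kept_internal))
  if (!is.null(el)) out$edge.length <- el
  if (!is.null(tree$node.label)) {
    out$node.label <- tree$node.label[kept_internal - ntip]
  }
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Node ages of an ultrametric tree
#'
#' @param tree an ultrametric `phylo`.
#' @return numeric vector of ages (time before present, same units as edge
#'   lengths) indexed by node id; tips are 0.
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Check ultrametricity
#'
#' @param tree a `phylo`.
#' @param tol relative tolerance on tip depths.
#' @return logical.
#' @export
is_chronogram <- function(tree, tol = 1e-9) {
  if (is.null(tree$edge.length)) return(FALSE)
  depths <- ape::node.depth.edgelength(tree)
  tips <- depths[seq_len(length(tree$tip.label))]
  diff(range(tips)) <= tol * max(tips)
}

#' Build a chronogram from a topology and clade ages
#'
#' Assigns an age (Ma before present) to every internal node and returns the
#' ultrametric tree. Ages are supplied as a list of `list(clade =, age =)`
#' entries; each clade is matched to the node subtending exactly those taxa.
#' With `interpolate = TRUE`, internal nodes not covered by `ages` receive
#' ages spaced evenly between the nearest aged ancestor and the tips: an
#' unaged node at maximal chain depth k below its parent gets
#' `parent_age * k / (k + 1)`.
#'
#' @param topology a rooted `phylo`; branch lengths are ignored.
#' @param ages list of `list(clade = <character>, age = <Ma>)`.
#' @param interpolate fill unaged internal nodes (default FALSE: every
#'   internal node must be aged).
#' @return an ultrametric `phylo` with heights in Ma.
#' @export
chronogram_from_ages <- function(topology, ages, interpolate = FALSE) {
  tree <- topology
  ntip <- length(tree$tip.label)
  masks <- node_masks(tree)
  node_age <- rep(NA_real_, ntip + tree$Nnode)
  node_age[seq_len(ntip)] <- 0
  for (a in ages) {
    m <- mask_of(a$clade, tree$tip.label)
    hit <- which(masks == m)
    if (!length(hit)) {
      stop("no node subtends clade {", paste(a$clade, collapse = ","), "}")
    }
    node_age[hit] <- a$age
  }
  if (anyNA(node_age)) {
    if (!interpolate) {
      stop(sum(is.na(node_age)), " internal node(s) without an age")
    }
    # max chain depth of unaged internal nodes below each node
    chain <- integer(ntip + tree$Nnode)
    edge <- ape::reorder.phylo(tree, "postorder")$edge
    for (i in seq_len(nrow(edge))) {
      p <- edge[i, 1]; c <- edge[i, 2]
      d <- chain[c] + as.integer(is.na(node_age[c]))
      chain[p] <- max(chain[p], d)
    }
    pre <- ape::reorder.phylo(tree, "cladewise")$edge
    for (i in seq_len(nrow(pre))) {
      p <- pre[i, 1]; c <- pre[i, 2]
      if (is.na(node_age[c])) {
        k <- chain[c] + 1L
        node_age[c] <- node_age[p] * k / (k + 1)
      }
    }
  }
  bad <- tree$edge[node_age[tree$edge[, 1]] <= node_age[tree$edge[, 2]], ,
                   drop = FALSE]
  if (nrow(bad)) {
    labs <- apply(bad, 1, function(e) {
      paste0("parent ", signif(node_age[e[1]], 6), " Ma <= child ",
             signif(node_age[e[2]], 6), " Ma")
    })
    stop("age ordering violated on ", nrow(bad), " edge(s): ",
         paste(labs, collapse = "; "))
  }
  tree$edge.length <- node_age[tree$edge[, 1]] - node_age[tree$edge[, 2]]
  tree$node.label <- NULL
  tree
}

#' Age of the most recent common ancestor of a taxon set
#'
#' @param tree an ultrametric `phylo`.
#' @param taxa character vector of tip labels (length 1 gives 0).
#' @return age in the tree's time units.
#' @export
mrca_age <- function(tree, taxa) {
  taxa <- unique(taxa)
  if (length(taxa) == 1) return(0)
  ages <- node_ages(tree)
  ages[ape::getMRCA(tree, taxa)]
}

# alignment containers --------------------------------------------------------

#' Construct an alignment
#'
#' Alignments are uppercase character matrices (taxa x sites) over
#' `A,C,G,T`, IUPAC ambiguity codes, `-` (gap) and `?` (missing), with an
#' optional partition scheme attached as attribute `"scheme"`.
#'
#' @param x character matrix with taxon rownames.
#' @param scheme optional [partition_scheme()].
#' @return the validated matrix, class `c("macroils_aln","matrix")`.
#' @export
alignment <- function(x, scheme = NULL) {
  stopifnot(is.matrix(x), is.character(x), !is.null(rownames(x)))
  rownames(x) <- trimws(rownames(x))
  if (anyDuplicated(rownames(x))) stop("duplicate taxon labels in alignment")
  x[] <- toupper(x)
  ok <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
          "B", "D", "H", "V", "N", "-", "?")
  bad <- setdiff(unique(as.vector(x)), ok)
  if (length(bad)) stop("invalid characters in alignment: ",
                        paste(bad, collapse = ", "))
  if (!is.null(scheme)) {
    if (max(scheme$end) > ncol(x)) stop("partition range exceeds alignment length")
    attr(x, "scheme") <- scheme
  }
  class(x) <- c("macroils_aln", class(x))
  x
}

#' Define a site-partition scheme
#'
#' Named site classes given by 1-based inclusive ranges, optionally expanded
#' by codon phase (the range start defines phase 1).
#'
#' @param ... named arguments; each is a 2-column matrix or a length-2 vector
#'   `c(start, end)`, or a list of such ranges.
#' @param codon named character vector: classes to expand into codon
#'   positions, e.g. `codon = c(ND1 = "pos")` creates `ND1_pos1..3`.
#' @return data.frame with columns `class`, `start`, `end`.
#' @export
partition_scheme <- function(..., codon = NULL) {
  defs <- list(...)
  if (is.null(names(defs)) || any(names(defs) == "")) {
    stop("all partition classes must be named")
  }
  rows <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    if (!is.list(d)) d <- list(d)
    for (r in d) {
      stopifnot(length(r) == 2, r[1] >= 1, r[2] >= r[1])
      if (!is.null(codon) && nm %in% names(codon)) {
        for (ph in 1:3) {
          rows[[length(rows) + 1L]] <- data.frame(
            class = paste0(nm, "_pos", ph), start = r[1] + ph - 1, end = r[2],
            by = 3)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          class = nm, start = r[1], end = r[2], by = 1)
      }
    }
  }
  out <- do.call(rbind, rows)
  out
}

#' Site indices of each partition class
#'
#' @param scheme a [partition_scheme()].
#' @param nsites alignment length (for bound checking).
#' @return named list of integer vectors, one per class.
#' @export
scheme_sites <- function(scheme, nsites = NULL) {
  out <- list()
  for (i in seq_len(nrow(scheme))) {
    s <- seq(scheme$start[i], scheme$end[i], by = scheme$by[i])
    cl <- scheme$class[i]
    out[[cl]] <- sort(unique(c(out[[cl]], s)))
  }
  if (!is.null(nsites)) {
    cover <- sort(unlist(out, use.names = FALSE))
    if (any(cover > nsites)) stop("partition range exceeds alignment bounds")
    if (anyDuplicated(cover)) stop("partition classes overlap")
  }
  out
}

# standard-format I/O ---------------------------------------------------------

#' Read a FASTA alignment
#' @param file path.
#' @return a [alignment()] matrix.
#' @export
read_fasta <- function(file) {
  d <- ape::read.FASTA(file)
  m <- toupper(as.character(as.matrix(d)))
  alignment(m)
}

#' Write a FASTA alignment
#' @param aln an [alignment()] matrix.
#' @param file path.
#' @export
write_fasta <- function(aln, file) {
  ape::write.FASTA(ape::as.DNAbin(tolower(unclass(aln))), file)
  invisible(file)
}

#' Read a relaxed PHYLIP alignment
#' @param file path.
#' @return a [alignment()] matrix.
#' @export
read_phylip <- function(file) {
  d <- phangorn::read.phyDat(file, format = "phylip", type = "DNA")
  alignment(toupper(as.character(d)))
}

#' Write a relaxed PHYLIP alignment
#' @param aln an [alignment()] matrix.
#' @param file path.
#' @export
write_phylip <- function(aln, file) {
  phangorn::write.phyDat(phangorn::phyDat(unclass(aln), type = "DNA"),
                         file, format = "phylip")
  invisible(file)
}

#' Read trees and charset partitions from a NEXUS file
#'
#' Trees are read with [ape::read.nexus()]. `charset` lines inside a sets or
#' assumptions block (`charset name = 1-300\3;` style, 1-based inclusive, an
#' optional `\\3` step) are parsed into a [partition_scheme()]-shaped
#' data.frame; no installed package exposes charset parsing.
#'
#' @param file path.
#' @return list with elements `trees` (multiPhylo or NULL) and `scheme`
#'   (data.frame or NULL).
#' @export
read_nexus_trees <- function(file) {
  txt <- readLines(file, warn = FALSE)
  trees <- NULL
  if (any(grepl("begin trees", txt, ignore.case = TRUE))) {
    trees <- ape::read.nexus(file)
  }
  cs <- grep("^\\s*charset\\s", txt, ignore.case = TRUE, value = TRUE)
  scheme <- NULL
  if (length(cs)) {
    rows <- list()
    for (line in cs) {
      line <- sub(";.*$", "", line)
      nm <- sub("^\\s*charset\\s+([^= \t]+)\\s*=.*$", "\\1", line,
                ignore.case = TRUE)
      body <- sub("^[^=]*=", "", line)
      for (piece in strsplit(trimws(body), "\\s+")[[1]]) {
        m <- regmatches(piece,
                        regexec("^(\\d+)(?:-(\\d+))?(?:\\\\(\\d+))?$", piece,
                                perl = TRUE))[[1]]
        if (length(m) == 0) stop("unparseable charset range: ", piece)
        s <- as.integer(m[2])
        e <- if (m[3] == "") s else as.integer(m[3])
        by <- if (m[4] == "") 1L else as.integer(m[4])
        rows[[length(rows) + 1L]] <-
          data.frame(class = nm, start = s, end = e, by = by)
      }
    }
    scheme <- do.call(rbind, rows)
  }
  list(trees = trees, scheme = scheme)
}

#' Root a tree on a named outgroup
#'
#' @param tree a `phylo`.
#' @param outgroup character vector of tip labels.
#' @return rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) stop("outgroup taxa missing: ",
                            paste(missing, collapse = ", "))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
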