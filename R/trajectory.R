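# Specificity-state classification, DFGx extraction and tree annotation.

#' Classify a +1 specificity state
#'
#' Maps a log2(+1R / +1P) ratio to one of three states: `R_pref` when the
#' ratio exceeds `threshold`, `P_pref` when below `-threshold`, else
#' `dual_PR`. The default threshold of 1 (a twofold difference) treats
#' kinases within twofold as dual-specific. Monotone in the ratio.
#'
#' @param log2_ratio numeric (vectorized).
#' @param threshold positive classification threshold on |log2 ratio|.
#' @return character vector in `c("P_pref", "dual_PR", "R_pref")` with
#'   attributes `log2_ratio` and `threshold`.
#' @export
classify_state <- function(log2_ratio, threshold = 1) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  lab <- ifelse(log2_ratio > threshold, "R_pref",
                ifelse(log2_ratio < -threshold, "P_pref", "dual_PR"))
  attr(lab, "log2_ratio") <- log2_ratio
  attr(lab, "threshold") <- threshold
  lab
}

#' Extract the DFGx residue from a kinase-domain sequence
#'
#' Finds the conserved DFG motif at the start of the activation loop and
#' returns the residue immediately C-terminal to it. When several DFG
#' matches exist, the one followed by an APE motif 15-45 residues
#' downstream (the activation-loop window, measured from the end of DFG to
#' the start of APE) is selected.
#'
#' @param sequence ungapped protein sequence (character scalar).
#' @param window activation-loop length window, in residues between DFG
#'   and APE.
#' @return list with `residue` (single character) and `index` (0-based
#'   position of the DFGx residue in the sequence).
#' @export
extract_dfgx <- function(sequence, window = c(15L, 45L)) {
  s <- toupper(gsub("-", "", sequence))
  dfg <- gregexpr("DFG", s, fixed = TRUE)[[1]]
  if (dfg[1] == -1L) stop("no DFG motif found", call. = FALSE)
  ape_pos <- gregexpr("APE", s, fixed = TRUE)[[1]]
  hit <- NA_integer_
  for (d in dfg) {
    gap <- ape_pos - (d + 3L)           # residues between DFG end and APE
    if (ape_pos[1] != -1L && any(gap >= window[1] & gap <= window[2])) {
      hit <- d
      break
    }
  }
  if (is.na(hit))
    stop("no DFG motif with an APE ", window[1], "-", window[2],
         " residues downstream", call. = FALSE)
  idx <- hit + 3L                        # 1-based position of DFGx
  if (idx > nchar(s)) stop("sequence ends at DFG", call. = FALSE)
  list(residue = substr(s, idx, idx), index = idx - 1L)
}

#' Map DFGx transitions onto a tree
#'
#' Extracts the DFGx residue for every node's sequence and reports each
#' parent-to-child branch on which the residue changes. Nodes whose
#' sequence lacks an extractable DFGx are flagged in the result, not
#' silently skipped.
#'
#' @param tree rooted ape `phylo`.
#' @param sequences named character vector of ungapped sequences covering
#'   tips and internal nodes (names are tip/node labels or ape ids).
#' @return list with `transitions` (data.frame: parent, child,
#'   from_residue, to_residue; node labels where available), `dfgx` (named
#'   residue per node) and `failed` (labels of nodes without a DFGx).
#' @export
map_dfgx_transitions <- function(tree, sequences) {
  ids <- vapply(names(sequences), function(n) resolve_node(tree, n), 0L)
  res <- rep(NA_character_, n_tips(tree) + tree$Nnode)
  failed <- character(0)
  for (i in seq_along(sequences)) {
    r <- tryCatch(extract_dfgx(sequences[[i]])$residue, error = function(e) NA)
    if (is.na(r)) failed <- c(failed, names(sequences)[i])
    res[ids[i]] <- r
  }
  tr <- data.frame(parent = character(0), child = character(0),
                   from_residue = character(0), to_residue = character(0))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    if (!is.na(res[p]) && !is.na(res[c_]) && res[p] != res[c_]) {
      tr <- rbind(tr, data.frame(parent = node_label(tree, p),
                                 child = node_label(tree, c_),
                                 from_residue = res[p],
                                 to_residue = res[c_]))
    }
  }
  names(res) <- vapply(seq_along(res), function(i) node_label(tree, i), "")
  list(transitions = tr, dfgx = res, failed = failed)
}

# ---- NHX annotated-tree text ------------------------------------------

nhx_escape <- function(x) gsub("[][(),:;=\\s]", "_", x, perl = TRUE)

#' Write and read trees with NHX annotations
#'
#' `annotate_tree()` renders a rooted tree as New Hampshire eXtended text:
#' plain Newick plus `[&&NHX:key=value:...]` comments carrying per-node
#' annotations (e.g. specificity state, log2 ratio, DFGx residue).
#' `read_nhx()` parses it back; the pair round-trips topology, labels,
#' branch lengths (to >= 10 significant digits) and all annotations.
#'
#' @param tree rooted ape `phylo`.
#' @param annotations optional data.frame with a `node` column (labels or
#'   ape ids) plus one column per tag; an empty/`NULL` value writes plain
#'   Newick.
#' @param path optional file to write.
#' @return `annotate_tree()`: the NHX string (invisibly when `path`
#'   given). `read_nhx()`: an ape `phylo` with attribute `annotations` (a
#'   data.frame: node label, tag columns).
#' @export
annotate_tree <- function(tree, annotations = NULL, path = NULL) {
  nn <- n_tips(tree) + tree$Nnode
  tags <- vector("list", nn)
  if (!is.null(annotations) && nrow(annotations)) {
    if (is.null(annotations$node))
      stop("annotations need a 'node' column", call. = FALSE)
    tagcols <- setdiff(names(annotations), "node")
    for (i in seq_len(nrow(annotations))) {
      id <- resolve_node(tree, annotations$node[i])
      vals <- annotations[i, tagcols, drop = FALSE]
      keep <- !vapply(vals, function(v) is.na(v), NA)
      tags[[id]] <- vapply(vals[keep], as.character, "")
    }
  }
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- tree$edge.length
  eidx <- stats::setNames(seq_len(nrow(tree$edge)), tree$edge[, 2])

  fmt_node <- function(id) {
    lab <- if (id <= n_tips(tree)) tree$tip.label[id]
           else if (!is.null(tree$node.label)) {
             l <- tree$node.label[id - n_tips(tree)]
             if (is.na(l)) "" else l
           } else ""
    out <- if (id > n_tips(tree)) {
      ch <- kids[[as.character(id)]]
      paste0("(", paste(vapply(ch, fmt_node, ""), collapse = ","), ")", lab)
    } else lab
    e <- eidx[as.character(id)]
    if (!is.na(e) && !is.null(elen))
      out <- paste0(out, ":", sprintf("%.12g", elen[e]))
    tg <- tags[[id]]
    if (length(tg))
      out <- paste0(out, "[&&NHX:",
                    paste(names(tg), tg, sep = "=", collapse = ":"), "]")
    out
  }
  txt <- paste0(fmt_node(root_id(tree)), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @param text NHX string (used when `path` is `NULL`).
#' @rdname annotate_tree
#' @export
read_nhx <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- gsub("\\s", "", text)
  # pull out the NHX comments, leaving plain newick with placeholders
  ann <- list()
  counter <- 0L
  plain <- ""
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(text, i, n), fixed = TRUE)
      com <- substr(text, i + 1L, i + j - 2L)
      i <- i + j
      if (startsWith(com, "&&NHX")) {
        counter <- counter + 1L
        kv <- strsplit(sub("^&&NHX:?", "", com), ":", fixed = TRUE)[[1]]
        kv <- kv[nzchar(kv)]
        parts <- strsplit(kv, "=", fixed = TRUE)
        tagv <- vapply(parts, function(p) paste(p[-1], collapse = "="), "")
        names(tagv) <- vapply(parts, `[[`, "", 1)
        ann[[counter]] <- tagv
        plain <- paste0(plain, "{", counter, "}")
      }
    } else {
      plain <- paste0(plain, ch)
      i <- i + 1L
    }
  }
  # attach placeholders to node positions: parse the decorated newick
  tree_txt <- gsub("\\{\\d+\\}", "", plain)
  tree <- ape::read.tree(text = tree_txt)
  if (!length(ann)) {
    attr(tree, "annotations") <- NULL
    return(tree)
  }
  # walk the decorated string in parallel with a fresh render of the tree:
  # instead, map placeholders to nodes by re-parsing node-by-node
  node_of_placeholder <- match_nhx_nodes(plain, tree)
  tags <- sort(unique(unlist(lapply(ann, names))))
  df <- data.frame(node = vapply(node_of_placeholder,
                                 function(id) node_label(tree, id), ""),
                   stringsAsFactors = FALSE)
  for (tg in tags)
    df[[tg]] <- vapply(ann, function(a)
      if (tg %in% names(a)) a[[tg]] else NA_character_, "")
  attr(tree, "annotations") <- df
  tree
}

# Map each {k} placeholder in a decorated newick string to an ape node id.
# A placeholder sits immediately after a node's label/length, so we track
# which node each string position belongs to with a simple bracket parser.
match_nhx_nodes <- function(plain, tree) {
  nt <- n_tips(tree)
  tip_order <- character(0)
  # parse: maintain a stack; on "(" push new internal; on tip label record
  pos <- 1L
  n <- nchar(plain)
  # internal nodes close in the order of their ")" — same order ape uses
  # when reading: we record, for each placeholder, the most recently
  # completed node (tip or internal)
  placeholder_nodes <- integer(0)
  stack <- integer(0)
  internal_close_order <- 0L
  # first pass of ape numbering: tips numbered by appearance; internals by
  # preorder. Recover preorder index by simulating ape::read.tree numbering
  # via match of subtree strings is overkill; instead use cladewise order:
  # internals in ape::read.tree are numbered in the order their "(" opens.
  tip_count <- 0L
  open_count <- 0L
  open_ids <- integer(0)
  last_node <- NA_integer_
  i <- 1L
  while (i <= n) {
    ch <- substr(plain, i, i)
    if (ch == "(") {
      open_count <- open_count + 1L
      open_ids <- c(open_ids, nt + open_count)
      i <- i + 1L
    } else if (ch == ")") {
      last_node <- open_ids[length(open_ids)]
      open_ids <- open_ids[-length(open_ids)]
      i <- i + 1L
      # consume label and length following ")"
      j <- i
      while (j <= n && !substr(plain, j, j) %in% c(",", ")", ";", "{", "("))
        j <- j + 1L
      i <- j
    } else if (ch == "{") {
      j <- regexpr("}", substr(plain, i, n), fixed = TRUE)
      k <- as.integer(substr(plain, i + 1L, i + j - 2L))
      placeholder_nodes[k] <- last_node
      i <- i + j
    } else if (ch %in% c(",", ";")) {
      i <- i + 1L
    } else {
      # a tip label (possibly with :length)
      j <- i
      while (j <= n && !substr(plain, j, j) %in% c(",", ")", ";", "{", "("))
        j <- j + 1L
      tok <- substr(plain, i, j - 1L)
      lab <- sub(":.*$", "", tok)
      tip_count <- tip_count + 1L
      last_node <- match(lab, tree$tip.label)
      if (is.na(last_node))
        stop("cannot match tip label '", lab, "' while reading NHX",
             call. = FALSE)
      i <- j
    }
  }
  placeholder_nodes
}
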