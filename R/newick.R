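## Newick I/O with NHX-style bracket annotations.
##
## The dialect: standard rooted binary Newick; removal labels are carried in
## comments of the form [&rm=0] / [&rm=1] attached to a node (absent label
## means "unknown").  Sampled ancestors are accepted in either of the two
## common encodings -- a zero-length-branch child tip, or a degree-2 node --
## and normalized internally to degree-2 nodes.  An optional [&offset=x]
## comment before the closing semicolon anchors the youngest tip at age x
## (default 0: the youngest tip defines the present).  This parser is
## written in-package because removal-label comments must survive parsing,
## which general-purpose Newick readers do not guarantee.

parseNewickTokens <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  n <- nchar(text)
  pos <- 1L
  peek <- function() if (pos <= n) substr(text, pos, pos) else ""
  takeComment <- function() {
    ## returns named character vector of key=value pairs inside [&...]
    out <- character()
    while (peek() == "[") {
      close <- regexpr("]", substr(text, pos, n), fixed = TRUE)
      if (close < 0) stop("unterminated comment in Newick string")
      body <- substr(text, pos + 1L, pos + close - 2L)
      pos <<- pos + close
      body <- sub("^&", "", body)
      if (nzchar(body)) {
        for (kv in strsplit(body, ",", fixed = TRUE)[[1L]]) {
          eq <- strsplit(kv, "=", fixed = TRUE)[[1L]]
          if (length(eq) == 2L) out[eq[1L]] <- eq[2L]
        }
      }
    }
    out
  }
  takeLabel <- function() {
    start <- pos
    while (pos <= n && !substr(text, pos, pos) %in%
             c("(", ")", ",", ":", ";", "[")) pos <<- pos + 1L
    substr(text, start, pos - 1L)
  }
  takeLength <- function() {
    if (peek() != ":") return(NA_real_)
    pos <<- pos + 1L
    start <- pos
    while (pos <= n && grepl("[-0-9.eE+]", substr(text, pos, pos)))
      pos <<- pos + 1L
    as.numeric(substr(text, start, pos - 1L))
  }

  rows <- list()
  nid <- 0L
  parseClade <- function(parent) {
    nid <<- nid + 1L
    id <- nid
    nkids <- 0L
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parseClade(id)
        nkids <- nkids + 1L
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick string near position ", pos)
      }
    }
    label <- takeLabel()
    ann <- takeComment()
    len <- takeLength()
    ann <- c(ann, takeComment())
    rows[[id]] <<- list(id = id, parent = parent, brlen = len,
                        label = label, nkids = nkids,
                        rm = if ("rm" %in% names(ann))
                               as.integer(ann[["rm"]]) else NA_integer_,
                        off = if ("offset" %in% names(ann))
                                as.numeric(ann[["offset"]]) else NA_real_)
    id
  }
  parseClade(NA_integer_)
  offsetAnn <- takeComment()
  if (peek() != ";") stop("Newick string must end with ';'")
  offs <- c(vapply(rows, `[[`, numeric(1), "off"),
            if ("offset" %in% names(offsetAnn))
              as.numeric(offsetAnn[["offset"]]) else NA_real_)
  offs <- offs[!is.na(offs)]
  list(rows = rows, offset = if (length(offs)) offs[1L] else NA_real_)
}

#' Read a reconstructed tree from Newick
#'
#' Parses a rooted binary time-calibrated Newick tree carrying removal
#' labels as `[&rm=0]`/`[&rm=1]` comments; a node without a label has
#' unknown removal status.  Sampled ancestors may be encoded either as
#' degree-2 nodes or as zero-length-branch child tips; both are normalized
#' to degree-2 nodes.  Node ages are computed from the branch lengths with
#' the youngest tip anchored at age `presentOffset` (default 0, i.e. the
#' present); a trailing `[&offset=x]` comment in the file overrides the
#' default.  Tips whose resulting age is (numerically) the present are
#' classified as rho-sampled present-day tips; all older tips are ancient
#' psi-leaves.
#'
#' @param text a Newick string (exclusive with `file`).
#' @param file path to a file containing one Newick tree.
#' @param presentOffset age of the youngest tip; overrides any in-file
#'   annotation when given.
#' @param ageTol absolute tolerance used to recognize present-day tips and
#'   zero-length sampled-ancestor branches.
#' @return a [ReconTree-class] object.
#' @examples
#' tr <- readReconTree("((A:1,B:0.5[&rm=1]):1);")
#' treeNodes(tr)
#' @export
readReconTree <- function(text = NULL, file = NULL, presentOffset = NULL,
                          ageTol = 1e-8) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  parsed <- parseNewickTokens(text)
  rows <- parsed$rows
  nd <- data.frame(
    id = vapply(rows, `[[`, integer(1), "id"),
    parent = vapply(rows, `[[`, integer(1), "parent"),
    brlen = vapply(rows, `[[`, numeric(1), "brlen"),
    label = vapply(rows, `[[`, character(1), "label"),
    nkids = vapply(rows, `[[`, integer(1), "nkids"),
    rm = vapply(rows, `[[`, integer(1), "rm"),
    stringsAsFactors = FALSE)
  if (any(nd$nkids > 2L))
    stop("non-binary internal node: the model requires a binary tree")
  if (any(!is.na(nd$brlen) & nd$brlen < 0))
    stop("negative branch length")
  nd$brlen[is.na(nd$brlen)] <- 0

  ## depths: parents always precede children in parse order
  nd$depth <- 0
  for (j in seq_len(nrow(nd))[-1L])
    nd$depth[j] <- nd$depth[match(nd$parent[j], nd$id)] + nd$brlen[j]

  offset <- if (!is.null(presentOffset)) presentOffset
            else if (!is.na(parsed$offset)) parsed$offset else 0
  maxTip <- max(nd$depth[nd$nkids == 0L])
  nd$age <- maxTip - nd$depth + offset
  if (any(nd$age < -ageTol)) stop("negative node age")
  nd$age[abs(nd$age) < ageTol] <- 0

  ## an unannotated degree-1 root is a plain stem wrapper (e.g. "(A:2);"),
  ## not a sampled ancestor: collapse it
  if (nd$nkids[1L] == 1L && is.na(nd$rm[1L]) && !nzchar(nd$label[1L]) &&
      nrow(nd) > 1L) {
    child <- which(nd$parent == nd$id[1L])
    nd$parent[child] <- NA_integer_
    nd <- nd[-1L, , drop = FALSE]
  }

  ## normalize zero-length-branch child tips to degree-2 sampled ancestors
  zl <- which(nd$nkids == 0L & nd$brlen <= ageTol & !is.na(nd$parent) &
                nd$age > ageTol)
  drop <- integer()
  for (j in zl) {
    pj <- match(nd$parent[j], nd$id)
    if (nd$nkids[pj] != 2L)
      stop("zero-length branch attached to a non-branching node")
    nd$nkids[pj] <- 1L
    nd$rm[pj] <- nd$rm[j]
    if (!nzchar(nd$label[pj])) nd$label[pj] <- nd$label[j]
    drop <- c(drop, j)
  }
  if (length(drop)) nd <- nd[-drop, , drop = FALSE]

  ## offset > 0 means even the youngest tip is ancient: no present-day tips
  role <- ifelse(nd$nkids == 2L, "branching",
          ifelse(nd$nkids == 1L, "sampled_ancestor",
          ifelse(nd$age <= ageTol, "tip_present", "leaf")))
  status <- rep(NA_character_, nrow(nd))
  status[role == "leaf"] <-
    c("non_removed", "removed")[nd$rm[role == "leaf"] + 1L]
  status[role == "leaf" & is.na(nd$rm)] <- "unknown"
  if (any(role == "sampled_ancestor" & !is.na(nd$rm) & nd$rm == 1L))
    stop("a sampled ancestor cannot be labeled as removed")
  status[role == "sampled_ancestor"] <- "non_removed"

  new("ReconTree",
      nodes = data.frame(id = nd$id, parent = nd$parent, age = nd$age,
                         role = role, status = status, label = nd$label,
                         stringsAsFactors = FALSE),
      presentOffset = offset)
}

#' Write a reconstructed tree to Newick
#'
#' Inverse of [readReconTree()]: removal labels become `[&rm=.]` comments
#' (unknown status is written without a comment), sampled ancestors are
#' written as zero-length-branch child tips, and a non-zero present offset
#' is recorded as a trailing `[&offset=x]` comment.
#'
#' @param tree a [ReconTree-class] object.
#' @param file optional path; when NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeReconTree <- function(tree, file = NULL) {
  nd <- tree@nodes
  kidsOf <- split(nd$id, factor(nd$parent, levels = nd$id))
  fmtNum <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  ann <- function(i) {
    st <- nd$status[i]
    if (is.na(st) || st == "unknown") ""
    else sprintf("[&rm=%d]", as.integer(st == "removed"))
  }
  emit <- function(i, parentAge) {
    row <- match(i, nd$id)
    brl <- if (is.na(parentAge)) "" else
      paste0(":", fmtNum(parentAge - nd$age[row]))
    kids <- kidsOf[[as.character(i)]]
    lab <- nd$label[row]
    if (nd$role[row] %in% c("tip_present", "leaf")) {
      paste0(lab, ann(row), brl)
    } else if (nd$role[row] == "sampled_ancestor") {
      paste0("(", emit(kids[1L], nd$age[row]), ",",
             lab, "[&rm=0]:0)", brl)
    } else {
      paste0("(", emit(kids[1L], nd$age[row]), ",",
             emit(kids[2L], nd$age[row]), ")", brl)
    }
  }
  root <- nd$id[is.na(nd$parent)]
  off <- if (tree@presentOffset > 0)
    sprintf("[&offset=%s]", fmtNum(tree@presentOffset)) else ""
  out <- paste0(emit(root, NA), off, ";")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}
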