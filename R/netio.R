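# Plain-text readers/writers for the field's simple tabular formats.
# All formats are whitespace-delimited; lines starting with "#" and blank
# lines are ignored; node identity is case-sensitive exact string match.

read_data_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(lines = raw[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read a PPI network from a two-column edge list
#'
#' Each non-comment line names one interaction: two whitespace-separated
#' protein labels (extra tokens are ignored). Self-loops are dropped with a
#' warning, reciprocal duplicates collapse to one undirected edge, and node
#' order is first-appearance order. A disconnected network is reported with
#' a warning but accepted: real PPI extracts are rarely fully connected and
#' the downstream machinery copes with multiple components.
#'
#' @param path Path to the edge-list file.
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path) {
  dat <- read_data_lines(path)
  fields <- split_fields(dat$lines)
  short <- lengths(fields) < 2L
  if (any(short)) {
    abort(sprintf(
      "parse error in '%s': line %d has fewer than 2 fields",
      path, dat$lineno[which(short)[1]]
    ))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  net <- ppi_network(data.frame(from = from, to = to))
  nc <- n_components(net)
  if (nc > 1L) {
    warn(sprintf("network in '%s' is disconnected (%d components)", path, nc))
  }
  net
}

#' Read a cross-network similarity table
#'
#' Three whitespace-separated columns: a protein of the first network, a
#' protein of the second network, and a score. In `mode = "normalized"` the
#' score must already lie in \[0, 1\]. In `mode = "bitscore"` the file holds
#' raw BLAST bit scores; lines whose two labels are identical are read as
#' self-scores BLAST(x, x), and every cross score is normalized to
#' BLAST(u, v) / sqrt(BLAST(u, u) * BLAST(v, v)) via
#' [normalize_bit_scores()], which maps self-similarity to exactly 1.
#'
#' Duplicate lines for the same pair keep the maximum score (with a warning)
#' — a conservative merge of redundant BLAST hits, including bidirectional
#' u->v / v->u reports. Zero scores are dropped.
#'
#' @param path Path to the similarity file.
#' @param net1,net2 The two networks ([ppi_network()] or edge data frames);
#'   the first/second label of each line must belong to `net1`/`net2`.
#' @param mode `"normalized"` (default) or `"bitscore"`.
#' @return A tibble with columns `node1`, `node2`, `score`, all scores in
#'   (0, 1\].
#' @export
read_similarity <- function(path, net1, net2, mode = c("normalized", "bitscore")) {
  mode <- match.arg(mode)
  net1 <- as_ppi_network(net1)
  net2 <- as_ppi_network(net2)
  dat <- read_data_lines(path)
  fields <- split_fields(dat$lines)
  short <- lengths(fields) < 3L
  if (any(short)) {
    abort(sprintf(
      "parse error in '%s': line %d has fewer than 3 fields",
      path, dat$lineno[which(short)[1]]
    ))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(s)) {
    abort(sprintf(
      "parse error in '%s': non-numeric score on line %d",
      path, dat$lineno[which(is.na(s))[1]]
    ))
  }

  if (mode == "bitscore") {
    is_self <- a == b
    self_scores <- s[is_self]
    names(self_scores) <- a[is_self]
    if (anyDuplicated(a[is_self])) {
      warn("duplicate self-score lines: keeping the maximum")
      self_scores <- tapply(s[is_self], a[is_self], max)
    }
    a <- a[!is_self]
    b <- b[!is_self]
    s <- s[!is_self]
    missing_self <- setdiff(unique(c(a, b)), names(self_scores))
    if (length(missing_self) > 0) {
      abort(sprintf(
        "bitscore mode: missing self-score for %s",
        paste(head(missing_self, 5), collapse = ", ")
      ))
    }
    s <- normalize_bit_scores(s, self_scores[a], self_scores[b])
  } else {
    if (any(s < 0 | s > 1)) {
      abort(sprintf(
        "normalized similarity scores must lie in [0, 1]; offending value %g",
        s[which(s < 0 | s > 1)[1]]
      ))
    }
  }

  bad1 <- setdiff(a, net1$nodes)
  bad2 <- setdiff(b, net2$nodes)
  if (length(bad1) > 0 || length(bad2) > 0) {
    abort(sprintf(
      "similarity labels not found in their networks: %s",
      paste(head(c(bad1, bad2), 5), collapse = ", ")
    ))
  }

  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    warn("duplicate similarity pairs: keeping the maximum score")
    s <- as.numeric(tapply(s, key, max)[unique(key)])
    first <- !duplicated(key)
    a <- a[first]
    b <- b[first]
  }
  keep <- s > 0
  tibble(node1 = a[keep], node2 = b[keep], score = s[keep])
}

#' Read reference protein complexes
#'
#' One complex per line: `name<TAB>member1 member2 ...`. Complexes with
#' fewer than two members are dropped with a warning (a one-protein
#' "complex" can never be matched at the neighbor-affinity threshold).
#'
#' @param path Path to the complex file.
#' @return A tibble with columns `complex` (character) and `members`
#'   (list of character vectors).
#' @export
read_complexes <- function(path) {
  dat <- read_data_lines(path)
  parts <- strsplit(dat$lines, "\t")
  short <- lengths(parts) < 2L
  if (any(short)) {
    abort(sprintf(
      "parse error in '%s': line %d has no member field",
      path, dat$lineno[which(short)[1]]
    ))
  }
  name <- vapply(parts, `[[`, "", 1L)
  members <- lapply(parts, function(p) {
    unique(strsplit(trimws(p[[2]]), "[ \t]+")[[1]])
  })
  small <- lengths(members) < 2L
  if (any(small)) {
    warn(sprintf("dropping %d complex(es) with fewer than 2 members", sum(small)))
  }
  tibble(complex = name[!small], members = members[!small])
}

#' Read flat GO-style annotations
#'
#' One term per line: `term<TAB>root_size<TAB>member1 member2 ...`, where
#' `root_size` is the number of annotated proteins in the term's GO category
#' (the denominator of the information content). No DAG propagation is done;
#' terms are consumed as flat protein sets.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `term`, `root_size`, `members` (list).
#' @export
read_annotations <- function(path) {
  dat <- read_data_lines(path)
  parts <- strsplit(dat$lines, "\t")
  short <- lengths(parts) < 3L
  if (any(short)) {
    abort(sprintf(
      "parse error in '%s': line %d needs term, root size, members",
      path, dat$lineno[which(short)[1]]
    ))
  }
  term <- vapply(parts, `[[`, "", 1L)
  root_size <- as.integer(vapply(parts, `[[`, "", 2L))
  members <- lapply(parts, function(p) {
    unique(strsplit(trimws(p[[3]]), "[ \t]+")[[1]])
  })
  if (anyNA(root_size)) abort("non-integer root size")
  if (any(lengths(members) > root_size)) {
    abort("a term annotates more proteins than its root category size")
  }
  tibble(term = term, root_size = root_size, members = members)
}

#' Write a clustering to a plain-text file
#'
#' One line per non-empty cluster: `clusterID<TAB>member1 member2 ...`,
#' clusters ordered by id, members in input node order. The written file
#' round-trips through [read_clusters()].
#'
#' @param x An `asmodel_fit` or a data frame with columns `node` and
#'   `cluster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path) {
  assignment <- if (inherits(x, "asmodel_fit")) x$assignment else as_tibble(x)
  if (!all(c("node", "cluster") %in% names(assignment))) {
    abort("need columns `node` and `cluster`")
  }
  ids <- sort(unique(assignment$cluster))
  lines <- vapply(ids, function(h) {
    members <- assignment$node[assignment$cluster == h]
    paste0(h, "\t", paste(members, collapse = " "))
  }, "")
  con <- file(path, "wb") # fixed "\n" endings: identical bytes on any platform
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a clustering written by [write_clusters()]
#'
#' @param path Path to the cluster file.
#' @return A tibble with columns `node` and `cluster` (integer when all ids
#'   are integral, character otherwise).
#' @export
read_clusters <- function(path) {
  dat <- read_data_lines(path)
  parts <- strsplit(dat$lines, "\t")
  ids <- vapply(parts, `[[`, "", 1L)
  members <- lapply(parts, function(p) strsplit(trimws(p[[2]]), "[ \t]+")[[1]])
  out <- tibble(
    node = unlist(members),
    cluster = rep(ids, lengths(members))
  )
  if (!anyNA(suppressWarnings(as.integer(ids)))) {
    out$cluster <- as.integer(out$cluster)
  }
  out
}
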