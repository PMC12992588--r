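# GFF3 reading (CDS features only) and Newick tree pruning.
# All genomic coordinates are 1-based inclusive end-to-end, per the GFF3
# standard; protein coordinates elsewhere in the package follow suit.

#' Read CDS features from a GFF3 file
#'
#' Only `CDS` features are retained (rRNA/tRNA/pseudogenes do not take part
#' in the downstream-gene analysis). Features are returned sorted by
#' (contig, start). The free-text product annotation is taken from the
#' `product` attribute (empty string when absent); the protein identifier
#' from `protein_id`, falling back to `ID`.
#'
#' @param path Path to a GFF3 file. An embedded `##FASTA` section, if any,
#'   is ignored.
#' @return data.frame with columns `feature_id`, `contig`, `start`, `end`,
#'   `strand`, `product_annotation`, `protein_id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(startsWith(lines, "##FASTA"))
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1L] - 1L)]
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  bad <- body[nfield != 9L]
  if (length(bad))
    stop("malformed GFF3 '", path, "': expected 9 tab-separated columns ",
         "at line ", bad[1L], " (found ", nfield[match(bad[1L], body)], ")")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (length(gr) == 0L) {
    return(data.frame(feature_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), product_annotation = character(),
                      protein_id = character(), stringsAsFactors = FALSE))
  }
  md <- S4Vectors::mcols(gr)
  grab <- function(field) {
    if (field %in% names(md)) {
      v <- as.character(md[[field]])
      v[is.na(v)] <- ""
      v
    } else rep("", length(gr))
  }
  id <- grab("ID")
  pid <- grab("protein_id")
  pid[!nzchar(pid)] <- id[!nzchar(pid)]
  out <- data.frame(feature_id = ifelse(nzchar(id), id,
                                        paste0("cds", seq_along(gr))),
                    contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    product_annotation = grab("product"),
                    protein_id = pid,
                    stringsAsFactors = FALSE)
  if (any(!out$strand %in% c("+", "-")))
    stop("GFF3 '", path, "': CDS feature with strand neither '+' nor '-'")
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune a Newick tree to a set of leaves
#'
#' Retains exactly the requested leaves; unary internal nodes created by the
#' pruning are collapsed with branch lengths summed along the collapsed
#' path, so root-to-tip path lengths of retained leaves are preserved.
#'
#' @param newick_text A Newick string (with branch lengths).
#' @param keep Character vector of leaf labels to retain (non-empty subset
#'   of the tree's leaves).
#' @return A Newick string over exactly the `keep` leaves.
#' @examples
#' prune_tree("((A:1,B:1):1,C:2);", c("A", "C")) # "(A:2,C:2);"
#' @export
prune_tree <- function(newick_text, keep) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  keep <- unique(as.character(keep))
  if (!length(keep)) stop("'keep' must name at least one leaf")
  tr <- ape::read.tree(text = newick_text)
  if (is.null(tr)) stop("could not parse Newick text")
  missing <- setdiff(keep, tr$tip.label)
  if (length(missing))
    stop("labels absent from the tree: ", paste(missing, collapse = ", "))
  if (length(keep) == 1L) {
    # degenerate single-leaf tree: ape cannot represent it as "phylo";
    # emit the leaf with its root-to-tip path length.
    depths <- node_depths(tr)
    len <- depths[match(keep, tr$tip.label)]
    return(sprintf("(%s:%s);", keep, format(len, trim = TRUE)))
  }
  # drop.tip with root.edge keeps basal branch lengths collapsed into the
  # root edge, so root-to-tip path lengths of retained leaves are preserved
  # keep.tip collapses unary nodes (summing branch lengths); the basal
  # path from the old root to the MRCA of the kept leaves is preserved as
  # the pruned tree's root edge, so root-to-tip path lengths survive
  stem <- if (is.null(tr$root.edge)) 0 else tr$root.edge
  mrca <- ape::getMRCA(tr, keep)
  if (!is.null(mrca))
    stem <- stem + ape::node.depth.edgelength(tr)[mrca]
  pruned <- ape::keep.tip(tr, keep)
  if (stem > 0) pruned$root.edge <- stem
  ape::write.tree(pruned)
}

# Root-to-tip path lengths for all tips, in tip order.
node_depths <- function(tr) {
  n_tip <- length(tr$tip.label)
  depth <- numeric(n_tip + tr$Nnode)
  root <- n_tip + 1L
  # edges are parent -> child; traverse in preorder
  ord <- ape::reorder.phylo(tr, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1L]; chi <- ord$edge[i, 2L]
    depth[chi] <- depth[par] + if (is.null(ord$edge.length)) 0 else ord$edge.length[i]
  }
  depth[seq_len(n_tip)]
}
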