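#' @import methods
#' @importFrom stats setNames median sd pchisq pnorm pt cor complete.cases
#'   dbinom rbinom rnorm runif
#' @importFrom utils head combn write.table read.table
NULL

GENE_COLS <- c("gene_id", "rank", "start", "end", "strand", "protein", "dna")

.empty_gene_table <- function() {
  data.frame(gene_id = character(), rank = integer(), start = integer(),
             end = integer(), strand = character(), protein = character(),
             dna = character(), stringsAsFactors = FALSE)
}

#' Replicon: an ordered, strand-aware set of genes on one DNA molecule
#'
#' A \code{Replicon} holds the gene models of a single chromosome, plasmid or
#' phage molecule. Genes are stored as a data frame ordered by \code{rank}
#' (0-based position in gene order along the molecule); coordinates are 1-based
#' inclusive. The replicon kind is taken from input metadata and never inferred.
#'
#' @slot repliconId character identifier, unique within a genome.
#' @slot kind one of \code{"chromosome"}, \code{"plasmid"}, \code{"phage"}.
#' @slot lengthBp molecule length in base pairs.
#' @slot circular logical; circular molecules wrap rank distances and
#'   neighborhoods, linear ones truncate at their ends.
#' @slot genes data.frame with columns \code{gene_id, rank, start, end, strand,
#'   protein, dna}.
#'
#' @exportClass Replicon
setClass("Replicon",
  representation(repliconId = "character", kind = "character",
                 lengthBp = "numeric", circular = "logical",
                 genes = "data.frame"))

setValidity("Replicon", function(object) {
  msg <- character()
  if (length(object@repliconId) != 1L || !nzchar(object@repliconId))
    msg <- c(msg, "repliconId must be a single non-empty string")
  if (!object@kind %in% c("chromosome", "plasmid", "phage"))
    msg <- c(msg, "kind must be chromosome, plasmid or phage")
  if (object@lengthBp <= 0) msg <- c(msg, "lengthBp must be positive")
  g <- object@genes
  if (!all(GENE_COLS %in% names(g)))
    msg <- c(msg, paste("genes must have columns:", paste(GENE_COLS, collapse = ", ")))
  if (nrow(g) > 0 && all(GENE_COLS %in% names(g))) {
    if (!identical(as.integer(g$rank), seq_len(nrow(g)) - 1L))
      msg <- c(msg, "ranks must be consecutive integers starting at 0")
    if (any(g$end < g$start)) msg <- c(msg, "gene end must be >= start")
    if (any(g$end > object@lengthBp)) msg <- c(msg, "gene coordinates exceed replicon length")
    if (!all(g$strand %in% c("+", "-"))) msg <- c(msg, "strand must be + or -")
    if (any(grepl("\\*.", g$protein))) msg <- c(msg, "protein contains internal stop")
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicated gene_id")
  }
  if (length(msg)) msg else TRUE
})

#' Genome: one or more replicons with a clade label
#'
#' @slot genomeId character identifier, unique within a dataset.
#' @slot clade character clade/species label used for per-clade summaries.
#' @slot replicons list of \linkS4class{Replicon}.
#'
#' @exportClass Genome
setClass("Genome",
  representation(genomeId = "character", clade = "character",
                 replicons = "list"))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  if (!all(vapply(object@replicons, is, logical(1), "Replicon")))
    msg <- c(msg, "replicons must all be Replicon objects")
  ids <- vapply(object@replicons, function(r) r@repliconId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated repliconId within genome")
  if (length(object@replicons) &&
      sum(vapply(object@replicons, function(r) r@lengthBp, numeric(1))) <= 0)
    msg <- c(msg, "total genome size must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn Replicon constructor
#' @param repliconId,kind,lengthBp,circular,genes slot values; \code{genes}
#'   rows are re-ordered by \code{start} and ranks reassigned from 0.
#' @export
Replicon <- function(repliconId, kind, lengthBp, circular = TRUE,
                     genes = .empty_gene_table()) {
  if (nrow(genes) > 0) {
    genes <- genes[order(genes$start, genes$end, genes$gene_id), , drop = FALSE]
    genes$rank <- seq_len(nrow(genes)) - 1L
    rownames(genes) <- NULL
  }
  new("Replicon", repliconId = as.character(repliconId), kind = kind,
      lengthBp = as.numeric(lengthBp), circular = circular,
      genes = genes[, GENE_COLS, drop = FALSE])
}

#' @describeIn Genome constructor
#' @param genomeId,clade,replicons slot values.
#' @export
Genome <- function(genomeId, clade = "unassigned", replicons = list()) {
  new("Genome", genomeId = as.character(genomeId), clade = as.character(clade),
      replicons = replicons)
}

## ---- generics and accessors -------------------------------------------------

#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @export
setGeneric("clade", function(x) standardGeneric("clade"))
#' @export
setGeneric("replicons", function(x) standardGeneric("replicons"))
#' @export
setGeneric("repliconId", function(x) standardGeneric("repliconId"))
#' @export
setGeneric("repliconKind", function(x) standardGeneric("repliconKind"))
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @export
setGeneric("geneTable", function(x, ...) standardGeneric("geneTable"))
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname Genome-class
setMethod("genomeId", "Genome", function(x) x@genomeId)
#' @rdname Genome-class
setMethod("clade", "Genome", function(x) x@clade)
#' @rdname Genome-class
setMethod("replicons", "Genome", function(x) x@replicons)
#' @rdname Replicon-class
setMethod("repliconId", "Replicon", function(x) x@repliconId)
#' @rdname Replicon-class
setMethod("repliconKind", "Replicon", function(x) x@kind)
#' @rdname Replicon-class
setMethod("isCircular", "Replicon", function(x) x@circular)
#' @rdname Replicon-class
setMethod("nGenes", "Replicon", function(x) nrow(x@genes))
#' @rdname Genome-class
setMethod("nGenes", "Genome", function(x)
  sum(vapply(x@replicons, nGenes, integer(1))))

#' @rdname Replicon-class
#' @param x object
#' @param ... unused
setMethod("geneTable", "Replicon", function(x, ...) {
  g <- x@genes
  if (nrow(g) == 0) return(cbind(data.frame(replicon_id = character()), g))
  cbind(data.frame(replicon_id = x@repliconId, stringsAsFactors = FALSE), g)
})

#' @rdname Genome-class
setMethod("geneTable", "Genome", function(x, ...) {
  tabs <- lapply(x@replicons, geneTable)
  out <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  if (is.null(out)) out <- cbind(data.frame(replicon_id = character()),
                                 .empty_gene_table())
  cbind(data.frame(genome_id = rep(x@genomeId, nrow(out)),
                   stringsAsFactors = FALSE), out)
})

#' @rdname Replicon-class
setMethod("genomeSize", "Replicon", function(x) x@lengthBp / 1e6)

#' Genome size in megabases (sum over replicons)
#' @rdname Genome-class
setMethod("genomeSize", "Genome", function(x)
  sum(vapply(x@replicons, function(r) r@lengthBp, numeric(1))) / 1e6)

setMethod("show", "Replicon", function(object) {
  cat(sprintf("Replicon %s (%s%s): %d bp, %d genes\n", object@repliconId,
              object@kind, if (object@circular) ", circular" else "",
              as.integer(object@lengthBp), nrow(object@genes)))
})

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome %s [clade %s]: %d replicon(s), %.3f Mb, %d genes\n",
              object@genomeId, object@clade, length(object@replicons),
              genomeSize(object), nGenes(object)))
  for (r in object@replicons) show(r)
})

## ---- genome sets ------------------------------------------------------------

#' A set of genomes analysed together
#'
#' Thin list container enforcing unique genome identifiers; most pipeline
#' stages take a \code{GenomeSet}.
#'
#' @slot genomes named list of \linkS4class{Genome}.
#' @exportClass GenomeSet
setClass("GenomeSet", representation(genomes = "list"))

setValidity("GenomeSet", function(object) {
  ids <- vapply(object@genomes, genomeId, character(1))
  msg <- character()
  if (!all(vapply(object@genomes, is, logical(1), "Genome")))
    msg <- c(msg, "all elements must be Genome objects")
  if (anyDuplicated(ids)) msg <- c(msg, "genome ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn GenomeSet constructor
#' @param genomes list of \linkS4class{Genome}
#' @export
GenomeSet <- function(genomes = list()) {
  ids <- vapply(genomes, genomeId, character(1))
  new("GenomeSet", genomes = setNames(genomes, ids))
}

#' @rdname GenomeSet-class
#' @param x a GenomeSet
#' @export
setMethod("length", "GenomeSet", function(x) length(x@genomes))

#' @rdname GenomeSet-class
#' @param i index or genome id
#' @export
setMethod("[[", "GenomeSet", function(x, i) x@genomes[[i]])

#' @rdname GenomeSet-class
#' @export
setMethod("names", "GenomeSet", function(x) names(x@genomes))

setMethod("show", "GenomeSet", function(object) {
  cat(sprintf("GenomeSet of %d genome(s); clades: %s\n", length(object@genomes),
              paste(unique(vapply(object@genomes, clade, character(1))),
                    collapse = ", ")))
})

#' @rdname GenomeSet-class
setMethod("geneTable", "GenomeSet", function(x, ...) {
  do.call(rbind, c(lapply(x@genomes, geneTable), list(make.row.names = FALSE)))
})

#' Find a replicon by id across a GenomeSet
#' @param gs GenomeSet
#' @param replicon_id replicon identifier
#' @return the Replicon, or an error if absent
#' @export
getReplicon <- function(gs, replicon_id) {
  for (g in gs@genomes) for (r in g@replicons)
    if (r@repliconId == replicon_id) return(r)
  stop("replicon not found: ", replicon_id)
}
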