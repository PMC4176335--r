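#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   readDNAStringSet writeXStringSet translate reverseComplement
#'   pairwiseAlignment nucleotideSubstitutionMatrix
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

.translate_cds <- function(dna) {
  cods <- .split_codons(toupper(dna))
  aa <- unname(.gc_table()[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## ---- reading ---------------------------------------------------------------

#' Read an annotated genome from GenBank or GFF3+FASTA
#'
#' CDS features are loaded per replicon and assigned 0-based ranks in
#' coordinate order. Genes flagged as partial, genes whose coding sequence does
#' not end in a stop codon, and genes whose translation carries an internal
#' stop are dropped and tallied in the load report (attribute
#' \code{"load_report"} on the returned \linkS4class{Genome}). Replicon kind
#' (chromosome/plasmid/phage) and circularity are read from file metadata,
#' never inferred from content.
#'
#' @param path file path: a (possibly multi-record) GenBank flat file, or a
#'   GFF3 file with a sibling FASTA (\code{<stem>.fna} or passed explicitly).
#' @param format \code{"genbank"} or \code{"gff3"}.
#' @param fasta path to the FASTA companion for GFF3 input; defaults to the
#'   GFF3 path with extension replaced by \code{.fna}.
#' @return a \linkS4class{Genome} with a \code{load_report} attribute
#'   (data.frame: replicon_id, retained, dropped_partial, dropped_no_stop,
#'   dropped_internal_stop).
#' @export
readAnnotatedGenome <- function(path, format = c("genbank", "gff3"),
                                fasta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "genbank") read_genbank_genome(path)
  else read_gff3_genome(path, fasta)
}

read_genbank_genome <- function(path) {
  lines <- readLines(path)
  rec_starts <- grep("^LOCUS ", lines)
  if (!length(rec_starts))
    stop("format error in ", path, ": no LOCUS record found")
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  reps <- list(); report <- list()
  genome_id <- NULL; clade_lab <- NULL
  for (i in seq_along(rec_starts)) {
    rec <- lines[rec_starts[i]:rec_ends[i]]
    parsed <- parse_genbank_record(rec, path, rec_starts[i])
    reps[[length(reps) + 1L]] <- parsed$replicon
    report[[length(report) + 1L]] <- parsed$report
    if (is.null(genome_id)) genome_id <- parsed$genome_id
    if (is.null(clade_lab)) clade_lab <- parsed$clade
  }
  g <- Genome(genome_id %||% basename(path), clade_lab %||% "unassigned", reps)
  attr(g, "load_report") <- do.call(rbind, report)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_genbank_record <- function(rec, path, line0) {
  locus <- strsplit(trimws(rec[1]), "[[:space:]]+")[[1]]
  if (length(locus) < 3)
    stop("format error in ", path, " line ", line0, ": malformed LOCUS line")
  rep_id <- locus[2]
  len_bp <- suppressWarnings(as.numeric(locus[3]))
  if (is.na(len_bp))
    stop("format error in ", path, " line ", line0, ": bad LOCUS length")
  circular <- any(grepl("circular", rec[1]))
  defn <- sub("^DEFINITION\\s+", "", grep("^DEFINITION", rec, value = TRUE)[1])
  if (is.na(defn)) defn <- ""
  kind <- if (grepl("\\bplasmid\\b", defn, ignore.case = TRUE)) "plasmid"
          else if (grepl("\\bphage\\b", defn, ignore.case = TRUE)) "phage"
          else "chromosome"
  fstart <- grep("^FEATURES", rec)
  ostart <- grep("^ORIGIN", rec)
  seq_str <- NULL
  if (length(ostart)) {
    oend <- grep("^//", rec)
    oend <- if (length(oend)) oend[1] - 1L else length(rec)
    seq_str <- toupper(gsub("[^A-Za-z]", "",
                            paste(rec[(ostart[1] + 1L):oend], collapse = "")))
  }
  feats <- if (length(fstart)) {
    lim <- if (length(ostart)) ostart[1] - 1L else length(rec)
    parse_genbank_features(rec[(fstart[1] + 1L):lim])
  } else list()
  organism <- NULL; strain <- NULL; plasmid_q <- FALSE
  genes <- list()
  n_partial <- 0L; n_nostop <- 0L; n_istop <- 0L
  for (f in feats) {
    if (f$key == "source") {
      organism <- f$qualifiers[["organism"]] %||% organism
      strain <- f$qualifiers[["strain"]] %||% strain
      if (!is.null(f$qualifiers[["plasmid"]])) plasmid_q <- TRUE
      next
    }
    if (f$key != "CDS") next
    if (f$partial || !is.null(f$qualifiers[["partial"]])) {
      n_partial <- n_partial + 1L; next
    }
    gid <- f$qualifiers[["locus_tag"]] %||% f$qualifiers[["protein_id"]]
    if (is.null(gid)) gid <- sprintf("%s_cds%04d", rep_id, length(genes) + 1L)
    dna <- NULL
    if (!is.null(seq_str) && f$end <= nchar(seq_str)) {
      dna <- substr(seq_str, f$start, f$end)
      if (f$strand == "-")
        dna <- as.character(reverseComplement(DNAString(dna)))
    }
    prot <- f$qualifiers[["translation"]]
    if (!is.null(dna) && nchar(dna) %% 3 == 0 && nchar(dna) >= 6) {
      last_codon <- substr(dna, nchar(dna) - 2, nchar(dna))
      if (!last_codon %in% STOP_CODONS) { n_nostop <- n_nostop + 1L; next }
      dna <- substr(dna, 1, nchar(dna) - 3)   # strip terminal stop
      if (is.null(prot)) prot <- .translate_cds(dna)
    }
    if (is.null(prot)) { n_partial <- n_partial + 1L; next }
    if (grepl("\\*", prot)) { n_istop <- n_istop + 1L; next }
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, rank = 0L, start = f$start, end = f$end,
      strand = f$strand, protein = prot, dna = dna %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  gt <- if (length(genes)) do.call(rbind, genes) else .empty_gene_table()
  if (nrow(gt) == 0L)
    warning("replicon ", rep_id, " has zero retained genes")
  if (plasmid_q) kind <- "plasmid"
  rep <- Replicon(rep_id, kind, len_bp, circular, gt)
  list(replicon = rep,
       report = data.frame(replicon_id = rep_id, retained = nrow(gt),
                           dropped_partial = n_partial,
                           dropped_no_stop = n_nostop,
                           dropped_internal_stop = n_istop,
                           stringsAsFactors = FALSE),
       genome_id = strain, clade = organism)
}

# Feature table parser: 5-space keys, 21-column continuation, /qual="..." with
# multi-line values (translation).
parse_genbank_features <- function(flines) {
  feats <- list(); cur <- NULL
  key_re <- "^ {5}(\\S+)\\s+(.*)$"
  for (ln in flines) {
    if (grepl(key_re, ln) && !grepl("^ {6,}", ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- finish_feature(cur)
      key <- sub(key_re, "\\1", ln)
      loc <- sub(key_re, "\\2", ln)
      cur <- list(key = key, loc = loc, quals = character())
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
      else if (length(cur$quals) == 0) cur$loc <- paste0(cur$loc, txt)
      else cur$quals[length(cur$quals)] <-
          paste0(cur$quals[length(cur$quals)], txt)
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- finish_feature(cur)
  feats
}

finish_feature <- function(cur) {
  loc <- cur$loc
  partial <- grepl("[<>]", loc)
  strand <- if (grepl("^complement", loc)) "-" else "+"
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  quals <- list()
  for (q in cur$quals) {
    m <- regmatches(q, regexec('^/([^=]+)=?"?([^"]*)"?$', q))[[1]]
    if (length(m) == 3) quals[[m[2]]] <- if (nzchar(m[3])) m[3] else TRUE
  }
  list(key = cur$key, start = if (length(nums)) min(nums) else NA,
       end = if (length(nums)) max(nums) else NA,
       strand = strand, partial = partial, qualifiers = quals)
}

## ---- GFF3 + FASTA ----------------------------------------------------------

read_gff3_genome <- function(path, fasta = NULL) {
  if (is.null(fasta)) fasta <- paste0(tools::file_path_sans_ext(path), ".fna")
  if (!file.exists(fasta)) stop("no FASTA companion found at ", fasta)
  seqs <- readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(grep("^##gff-version", lines)))
    stop("format error in ", path, ": missing ##gff-version pragma")
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9)
  if (length(bad))
    stop("format error in ", path, ": record ", bad[1], " lacks 9 columns")
  meta <- list()   # per-replicon kind/circular and genome labels
  genome_id <- NULL; clade_lab <- NULL
  rows <- list()
  n_partial <- setNames(integer(0), character(0))
  n_nostop <- n_istop <- n_partial
  bump <- function(v, k) { v[k] <- (if (k %in% names(v)) v[k] else 0L) + 1L; v }
  for (f in fields) {
    attrs <- parse_gff_attrs(f[9])
    sid <- f[1]
    if (f[3] == "region") {
      meta[[sid]] <- list(
        kind = attrs[["genome_kind"]] %||% "chromosome",
        circular = identical(attrs[["Is_circular"]], "true"))
      genome_id <- attrs[["genome_id"]] %||% genome_id
      clade_lab <- attrs[["clade"]] %||% clade_lab
      next
    }
    if (f[3] != "CDS") next
    if (!sid %in% names(n_partial)) {
      n_partial[sid] <- 0L; n_nostop[sid] <- 0L; n_istop[sid] <- 0L
    }
    if (identical(attrs[["partial"]], "true")) {
      n_partial <- bump(n_partial, sid); next
    }
    if (!sid %in% names(seqs))
      stop("format error: GFF3 seqid ", sid, " absent from FASTA")
    st <- as.integer(f[4]); en <- as.integer(f[5])
    dna <- as.character(seqs[[sid]][st:en])
    if (f[7] == "-") dna <- as.character(reverseComplement(DNAString(dna)))
    last_codon <- substr(dna, nchar(dna) - 2, nchar(dna))
    if (nchar(dna) %% 3 != 0 || !last_codon %in% STOP_CODONS) {
      n_nostop <- bump(n_nostop, sid); next
    }
    dna <- substr(dna, 1, nchar(dna) - 3)
    prot <- .translate_cds(dna)
    if (grepl("\\*", prot)) { n_istop <- bump(n_istop, sid); next }
    rows[[length(rows) + 1L]] <- data.frame(
      replicon = sid,
      gene_id = attrs[["ID"]] %||% sprintf("%s_cds%04d", sid, length(rows) + 1L),
      rank = 0L, start = st, end = en,
      strand = f[7], protein = prot, dna = dna, stringsAsFactors = FALSE)
  }
  gt <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(replicon = character()), .empty_gene_table())
  reps <- list(); report <- list()
  for (sid in names(seqs)) {
    sub <- gt[gt$replicon == sid, setdiff(names(gt), "replicon"), drop = FALSE]
    if (nrow(sub) == 0L) warning("replicon ", sid, " has zero retained genes")
    mk <- meta[[sid]] %||% list(kind = "chromosome", circular = TRUE)
    reps[[length(reps) + 1L]] <-
      Replicon(sid, mk$kind, length(seqs[[sid]]), mk$circular, sub)
    g0 <- function(v) if (sid %in% names(v)) unname(v[sid]) else 0L
    report[[length(report) + 1L]] <- data.frame(
      replicon_id = sid, retained = nrow(sub),
      dropped_partial = g0(n_partial), dropped_no_stop = g0(n_nostop),
      dropped_internal_stop = g0(n_istop), stringsAsFactors = FALSE)
  }
  g <- Genome(genome_id %||% basename(path), clade_lab %||% "unassigned", reps)
  attr(g, "load_report") <- do.call(rbind, report)
  g
}

parse_gff_attrs <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- list()
  for (p in kv) if (length(p) == 2) out[[p[1]]] <- utils::URLdecode(p[2])
  out
}

## ---- writing ---------------------------------------------------------------

# Replicon nucleotide sequence reconstructed from gene models: coding sequence
# (plus a TAA stop) on the annotated strand, intergenic gaps filled with a
# fixed ACGT tiling (intergenic content is never analysed downstream).
replicon_sequence <- function(rep) {
  n <- as.integer(rep@lengthBp)
  filler <- substr(strrep("ACGT", ceiling(n / 4)), 1, n)
  chars <- strsplit(filler, "")[[1]]
  g <- rep@genes
  for (i in seq_len(nrow(g))) {
    cds <- paste0(g$dna[i], "TAA")
    if (g$strand[i] == "-")
      cds <- as.character(reverseComplement(DNAString(cds)))
    chars[g$start[i]:g$end[i]] <- strsplit(cds, "")[[1]]
  }
  paste(chars, collapse = "")
}

#' Write a Genome as a multi-record GenBank flat file
#'
#' Each replicon becomes one record; CDS features carry \code{locus_tag} and
#' \code{translation} qualifiers, and the full reconstructed nucleotide
#' sequence is emitted under ORIGIN. The coding sequence is written with its
#' terminal stop codon, so files round-trip through
#' \code{\link{readAnnotatedGenome}}.
#'
#' @param genome a \linkS4class{Genome}; every gene needs a \code{dna} entry.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeGenomeGenBank <- function(genome, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character()
  for (rep in genome@replicons) {
    topo <- if (rep@circular) "circular" else "linear"
    out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %s BCT",
                          rep@repliconId, as.integer(rep@lengthBp), topo))
    out <- c(out, sprintf("DEFINITION  %s strain %s %s %s.", genome@clade,
                          genome@genomeId, rep@kind, rep@repliconId))
    out <- c(out, "FEATURES             Location/Qualifiers")
    out <- c(out, sprintf("     source          1..%d", as.integer(rep@lengthBp)))
    out <- c(out, sprintf('                     /organism="%s"', genome@clade))
    out <- c(out, sprintf('                     /strain="%s"', genome@genomeId))
    if (rep@kind == "plasmid")
      out <- c(out, sprintf('                     /plasmid="%s"', rep@repliconId))
    g <- rep@genes
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i], g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     CDS             %s", loc))
      out <- c(out, sprintf('                     /locus_tag="%s"', g$gene_id[i]))
      tr <- paste0('/translation="', g$protein[i], '"')
      st <- seq(1, nchar(tr), 58)
      out <- c(out, paste0("                     ",
                           substring(tr, st, pmin(st + 57, nchar(tr)))))
    }
    seq_str <- tolower(replicon_sequence(rep))
    out <- c(out, "ORIGIN")
    starts <- seq(1, nchar(seq_str), 60)
    for (s in starts) {
      chunk <- substr(seq_str, s, min(s + 59, nchar(seq_str)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, con)
  invisible(path)
}

#' Write a Genome as GFF3 plus FASTA
#'
#' Emits \code{<stem>.gff3} and \code{<stem>.fna}. Replicon kind, circularity
#' and the genome/clade labels are carried on per-replicon \code{region}
#' features so the pair round-trips through \code{\link{readAnnotatedGenome}}.
#'
#' @param genome a \linkS4class{Genome}.
#' @param stem output path stem (no extension).
#' @return invisibly, the GFF3 path.
#' @export
writeGenomeGFF3 <- function(genome, stem) {
  gff <- paste0(stem, ".gff3"); fna <- paste0(stem, ".fna")
  out <- "##gff-version 3"
  seqs <- character()
  for (rep in genome@replicons) {
    out <- c(out, sprintf("##sequence-region %s 1 %d", rep@repliconId,
                          as.integer(rep@lengthBp)))
    out <- c(out, paste(rep@repliconId, "rmscape", "region", 1,
                        as.integer(rep@lengthBp), ".", "+", ".",
                        sprintf("ID=%s;genome_id=%s;clade=%s;genome_kind=%s;Is_circular=%s",
                                rep@repliconId, genome@genomeId, genome@clade,
                                rep@kind, if (rep@circular) "true" else "false"),
                        sep = "\t"))
    g <- rep@genes
    for (i in seq_len(nrow(g)))
      out <- c(out, paste(rep@repliconId, "rmscape", "CDS", g$start[i],
                          g$end[i], ".", g$strand[i], "0",
                          sprintf("ID=%s", g$gene_id[i]), sep = "\t"))
    seqs[rep@repliconId] <- replicon_sequence(rep)
  }
  con <- file(gff, open = "wb"); writeLines(out, con); close(con)
  writeXStringSet(DNAStringSet(seqs), fna)
  invisible(gff)
}
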