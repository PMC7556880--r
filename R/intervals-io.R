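#' @importFrom GenomicRanges GRanges GRangesList reduce findOverlaps
#'   countOverlaps start end width strand strand<- seqnames mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlevels seqlengths seqinfo seqinfo<-
#'   seqnames
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet subseq
NULL

# All genomic coordinates cross the package boundary in BED convention
# (0-based half-open); internally intervals live in GRanges (1-based closed).
# bed [s, e)  <->  GRanges [s + 1, e].

#' Build a chromosome table
#'
#' @param chroms character vector of chromosome names (unique).
#' @param lengths positive integer lengths in bp.
#' @return a [GenomeInfoDb::Seqinfo] object used to bound-check all intervals.
#' @examples
#' chromTable(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
chromTable <- function(chroms, lengths) {
    if (anyDuplicated(chroms))
        stop("chromosome names must be unique")
    if (any(lengths <= 0))
        stop("chromosome lengths must be positive")
    Seqinfo(seqnames = as.character(chroms), seqlengths = as.integer(lengths))
}

#' Read / write a two-column chromosome-sizes table
#'
#' @param path TSV with columns chrom, length (no header).
#' @return [GenomeInfoDb::Seqinfo] (`readChromSizes`); invisible path
#'   (`writeChromSizes`).
#' @export
readChromSizes <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
        col.names = c("chrom", "length"),
        colClasses = c("character", "integer"))
    chromTable(tab$chrom, tab$length)
}

#' @rdname readChromSizes
#' @param chroms a `Seqinfo`.
#' @export
writeChromSizes <- function(chroms, path) {
    utils::write.table(
        data.frame(chrom = seqlevels(chroms),
            length = unname(seqlengths(chroms))),
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a genome FASTA into a sequence store
#'
#' @param path FASTA file.
#' @param chroms optional `Seqinfo`; when given, sequence lengths are checked
#'   against it.
#' @return a named [Biostrings::DNAStringSet], uppercased.
#' @export
readGenome <- function(path, chroms = NULL) {
    store <- readDNAStringSet(path)
    names(store) <- sub("\\s.*$", "", names(store))
    store <- DNAStringSet(toupper(store))
    if (!is.null(chroms)) {
        common <- intersect(names(store), seqlevels(chroms))
        bad <- common[BiocGenerics::width(store[common]) !=
            seqlengths(chroms)[common]]
        if (length(bad))
            stop("sequence length disagrees with chromosome table for: ",
                paste(bad, collapse = ", "))
    }
    store
}

#' Read BED3+ peaks into a GRanges
#'
#' Parses BED (0-based half-open) into a `GRanges` bound to `chroms`.  Lines on
#' chromosomes absent from `chroms`, or exceeding chromosome bounds, are an
#' error under `strict = TRUE` and are skipped with a warning otherwise.
#' Output is sorted by (chromosome, start).
#'
#' @param path BED file with >= 3 tab-separated columns; optional columns 4
#'   (name) and 6 (strand) are kept.
#' @param chroms a [GenomeInfoDb::Seqinfo] from [chromTable()] /
#'   [readChromSizes()].
#' @param strict reject (TRUE) or skip (FALSE) out-of-table lines.
#' @param label optional label stored in `metadata(gr)$label`.
#' @return a sorted `GRanges` with seqinfo `chroms`.
#' @export
readPeaks <- function(path, chroms, strict = TRUE, label = NULL) {
    if (!file.exists(path))
        stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        gr <- GRanges(seqinfo = chroms)
        S4Vectors::metadata(gr)$label <- label
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("malformed BED line %d: fewer than 3 fields",
            which(nf < 3L)[1L]))
    chrom <- vapply(fields, `[[`, character(1), 1L)
    s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (anyNA(s) || anyNA(e))
        stop(sprintf("malformed BED line %d: non-numeric coordinate",
            which(is.na(s) | is.na(e))[1L]))
    if (any(s >= e))
        stop(sprintf("invalid interval on line %d: start >= end",
            which(s >= e)[1L]))
    if (any(s < 0))
        stop(sprintf("invalid interval on line %d: negative start",
            which(s < 0)[1L]))
    name <- ifelse(nf >= 4L, vapply(fields, function(f)
        if (length(f) >= 4L) f[[4L]] else NA_character_, character(1)),
        NA_character_)
    std <- ifelse(nf >= 6L, vapply(fields, function(f)
        if (length(f) >= 6L) f[[6L]] else "*", character(1)), "*")
    std[!std %in% c("+", "-")] <- "*"

    known <- chrom %in% seqlevels(chroms)
    inb <- known
    inb[known] <- e[known] <= seqlengths(chroms)[chrom[known]]
    ok <- known & inb
    if (!all(ok)) {
        bad <- which(!ok)[1L]
        msg <- sprintf("line %d: interval %s:%d-%d outside chromosome table",
            bad, chrom[bad], s[bad], e[bad])
        if (strict) stop(msg) else warning("skipping ", sum(!ok),
            " line(s); first: ", msg)
    }
    gr <- GRanges(chrom[ok], IRanges(s[ok] + 1L, e[ok]), strand = std[ok],
        seqinfo = chroms)
    if (any(!is.na(name[ok])))
        names(gr) <- name[ok]
    gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
    S4Vectors::metadata(gr)$label <- label
    gr
}

#' Write a GRanges as BED
#'
#' Emits BED6 when names or strands are informative, BED3 otherwise;
#' coordinates are converted back to 0-based half-open so that
#' `readPeaks(writePeaks(x))` reproduces `x` exactly.
#'
#' @param peaks a `GRanges`.
#' @param path output path.
#' @return invisible `path`.
#' @export
writePeaks <- function(peaks, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(peaks) == 0L)
        return(invisible(path))
    s <- start(peaks) - 1L
    e <- end(peaks)
    std <- as.character(strand(peaks))
    hasName <- !is.null(names(peaks))
    hasStrand <- any(std %in% c("+", "-"))
    if (hasName || hasStrand) {
        nm <- if (hasName) names(peaks) else
            paste0("peak_", seq_along(peaks))
        std[std == "*"] <- "."
        out <- paste(as.character(seqnames(peaks)), s, e, nm, 0L, std,
            sep = "\t")
    } else {
        out <- paste(as.character(seqnames(peaks)), s, e, sep = "\t")
    }
    writeLines(out, con)
    invisible(path)
}

#' Merge replicate peak sets, keeping spans shared between replicates
#'
#' Overlapping intervals across the union of all replicates are merged into
#' maximal runs; a merged span is kept iff intervals from at least
#' `minSupport` distinct replicates contributed to it.  This is the
#' replicate-consolidation rule used to derive one final peak set per factor
#' from biological replicates.
#'
#' @param replicates list of `GRanges` (one per biological replicate).
#' @param minSupport minimum number of distinct supporting replicates
#'   (default 2).
#' @return a `GRanges` of merged, supported spans.
#' @examples
#' si <- chromTable("chr1", 1000)
#' r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), seqinfo = si)
#' r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150), seqinfo = si)
#' mergeReplicates(list(r1, r2))  # chr1:1-150
#' @export
mergeReplicates <- function(replicates, minSupport = 2L) {
    if (!length(replicates))
        stop("need at least one replicate")
    minSupport <- assertCount(minSupport, "minSupport")
    if (minSupport > length(replicates))
        stop("minSupport exceeds the number of replicates")
    merged <- reduce(unlist(GRangesList(lapply(replicates, function(g) {
        strand(g) <- "*"
        mcols(g) <- NULL
        names(g) <- NULL
        g
    }))), ignore.strand = TRUE)
    support <- Reduce(`+`, lapply(replicates, function(g)
        as.integer(countOverlaps(merged, g, ignore.strand = TRUE) > 0L)))
    merged[support >= minSupport]
}

#' Intersect two peak sets
#'
#' Counts each interval of `a` once however many `b` intervals it touches,
#' matching the convention that a co-occupancy fraction is a fraction of one
#' factor's peaks.
#'
#' @param a,b `GRanges` on the same chromosome table.
#' @param minBp minimum overlap in bp to count (default 1).
#' @return list with `overlap` (the `a` intervals overlapping `b`), `fracA`
#'   (their fraction of `a`) and `hits` (logical vector over `a`).
#' @export
intersectPeaks <- function(a, b, minBp = 1L) {
    minBp <- assertCount(minBp, "minBp")
    hits <- countOverlaps(a, b, minoverlap = minBp,
        ignore.strand = TRUE) > 0L
    list(overlap = a[hits],
        fracA = if (length(a)) sum(hits) / length(a) else NA_real_,
        hits = hits)
}

#' Read / write the gene-annotation TSV dialect
#'
#' Header columns: gene_id, chrom, strand, tss, start, end (tss/start/end in
#' 0-based bp, end exclusive).
#'
#' @param path TSV path.
#' @param chroms `Seqinfo`.
#' @return `GRanges` of gene bodies with mcols `gene_id` and `tss` (0-based).
#' @export
readGeneAnnotation <- function(path, chroms) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
        stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss", "start", "end")
    if (!all(need %in% names(tab)))
        stop("gene annotation must have columns: ",
            paste(need, collapse = ", "))
    if (anyDuplicated(tab$gene_id))
        stop("gene_id values must be unique")
    if (any(tab$tss < tab$start | tab$tss > tab$end))
        stop("each tss must lie within or at an end of its gene body")
    gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end),
        strand = tab$strand, seqinfo = chroms)
    mcols(gr)$gene_id <- tab$gene_id
    mcols(gr)$tss <- as.integer(tab$tss)
    gr
}

#' @rdname readGeneAnnotation
#' @param genes gene `GRanges` as returned by [readGeneAnnotation()].
#' @export
writeGeneAnnotation <- function(genes, path) {
    utils::write.table(
        data.frame(gene_id = mcols(genes)$gene_id,
            chrom = as.character(seqnames(genes)),
            strand = as.character(strand(genes)),
            tss = mcols(genes)$tss,
            start = start(genes) - 1L, end = end(genes)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Nearest upstream and downstream gene for each peak
#'
#' For each peak, finds the gene with the nearest TSS at or left of the peak
#' start (upstream in genome coordinates) and the nearest TSS at or right of
#' the peak end (downstream); a gene whose TSS falls inside the peak fills both
#' slots with distance 0.  Distances are non-negative edge-to-TSS bp.  Ties are
#' broken by the lexicographically smaller gene_id.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes gene `GRanges` with mcols `gene_id`, `tss` (0-based).
#' @return data.frame with one row per peak: peak, chrom, upstream_gene,
#'   upstream_dist, downstream_gene, downstream_dist (NA when no gene
#'   qualifies).
#' @export
nearestGenes <- function(peaks, genes) {
    if (!length(genes))
        stop("empty gene annotation")
    peakNames <- if (is.null(names(peaks)))
        paste0("peak_", seq_along(peaks)) else names(peaks)
    out <- data.frame(peak = peakNames,
        chrom = as.character(seqnames(peaks)),
        upstream_gene = NA_character_, upstream_dist = NA_real_,
        downstream_gene = NA_character_, downstream_dist = NA_real_,
        stringsAsFactors = FALSE)
    gchrom <- as.character(seqnames(genes))
    gid <- mcols(genes)$gene_id
    gtss <- mcols(genes)$tss
    noGene <- character(0)
    for (chr in unique(out$chrom)) {
        pi <- which(out$chrom == chr)
        gi <- which(gchrom == chr)
        if (!length(gi)) {
            noGene <- c(noGene, chr)
            next
        }
        # sort genes by (tss, gene_id) so ties resolve to the smaller id
        o <- gi[order(gtss[gi], gid[gi])]
        tss <- gtss[o]
        ids <- gid[o]
        for (j in pi) {
            s <- start(peaks)[j] - 1L   # bed start
            e <- end(peaks)[j]          # bed end (exclusive)
            inside <- which(tss >= s & tss < e)
            if (length(inside)) {
                g <- min(ids[inside])  # all at distance 0; smaller id wins
                out$upstream_gene[j] <- g
                out$downstream_gene[j] <- g
                out$upstream_dist[j] <- 0
                out$downstream_dist[j] <- 0
                next
            }
            up <- which(tss <= s)
            if (length(up)) {
                d <- s - tss[up]
                # last index among the minimal distances has the largest tss;
                # within equal tss the sort already puts the smaller id first
                k <- up[which(d == min(d))][1L]
                out$upstream_gene[j] <- ids[k]
                out$upstream_dist[j] <- s - tss[k]
            }
            dn <- which(tss >= e)
            if (length(dn)) {
                d <- tss[dn] - e
                k <- dn[which(d == min(d))][1L]
                out$downstream_gene[j] <- ids[k]
                out$downstream_dist[j] <- tss[k] - e
            }
        }
    }
    if (length(noGene))
        warning("no annotated gene on chromosome(s): ",
            paste(unique(noGene), collapse = ", "))
    out
}

#' Extract forward-strand peak sequences
#'
#' @param peaks `GRanges`.
#' @param store named `DNAStringSet` holding the chromosome sequences.
#' @return named `DNAStringSet`, one uppercased forward-strand sequence per
#'   peak, of width `end - start`.
#' @export
peakSequences <- function(peaks, store) {
    chr <- as.character(seqnames(peaks))
    missing <- setdiff(unique(chr), names(store))
    if (length(missing))
        stop("chromosome(s) absent from sequence store: ",
            paste(missing, collapse = ", "))
    lens <- BiocGenerics::width(store)[match(chr, names(store))]
    if (any(end(peaks) > lens))
        stop("peak extends beyond its chromosome sequence")
    seqs <- DNAStringSet(vapply(seq_along(peaks), function(i)
        as.character(subseq(store[[chr[i]]], start(peaks)[i], end(peaks)[i])),
        character(1)))
    names(seqs) <- if (is.null(names(peaks)))
        paste0("peak_", seq_along(peaks)) else names(peaks)
    seqs
}
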