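# Chromosome building: ordered, oriented scaffold parts per chromosome as
# AGP v2.1, corrected scaffold sequences, composition strings and the
# numbered karyotype / idiogram table.

#' Build chromosome-level AGP from oriented scaffold parts
#'
#' Components are laid centromere-to-telomere following
#' `order_on_chromosome`, separated by U gap rows of `gap_size` (linkage
#' evidence "map" — FISH placement is map evidence).
#'
#' @param parts part table from [split_and_orient()].
#' @param gap_size gap length in bases between consecutive components.
#' @return a `chromosome_build` data.frame in AGP v2.1 column layout:
#'   object, object_beg, object_end, part_number, component_type,
#'   component_id, component_beg, component_end, orientation (gap rows
#'   reuse columns 6-9 as gap_length, gap_type, linkage, evidence).
#' @export
build_chromosomes <- function(parts, gap_size = 100) {
  parts <- parts[!is.na(parts$assigned_chromosome), , drop = FALSE]
  rows <- list()
  for (ch in sort(unique(parts$assigned_chromosome))) {
    p <- parts[parts$assigned_chromosome == ch, , drop = FALSE]
    if (anyDuplicated(p$order_on_chromosome))
      stop("order collision on chromosome ", ch, ": two parts share rank ",
           p$order_on_chromosome[duplicated(p$order_on_chromosome)][1],
           call. = FALSE)
    p <- p[order(p$order_on_chromosome), , drop = FALSE]
    pos <- 0; pn <- 0
    for (i in seq_len(nrow(p))) {
      if (i > 1) {
        pn <- pn + 1
        rows[[length(rows) + 1L]] <- data.frame(
          object = ch, object_beg = pos + 1, object_end = pos + gap_size,
          part_number = pn, component_type = "U",
          component_id = as.character(gap_size), component_beg = "scaffold",
          component_end = "yes", orientation = "map",
          stringsAsFactors = FALSE)
        pos <- pos + gap_size
      }
      len <- p$end[i] - p$start[i]
      pn <- pn + 1
      ori <- p$orientation[i]
      rows[[length(rows) + 1L]] <- data.frame(
        object = ch, object_beg = pos + 1, object_end = pos + len,
        part_number = pn, component_type = "W",
        component_id = p$scaffold_id[i],
        component_beg = as.character(p$start[i] + 1),
        component_end = as.character(p$end[i]),
        orientation = if (is.na(ori)) "?" else ori,
        stringsAsFactors = FALSE)
      pos <- pos + len
    }
  }
  structure(do.call(rbind, rows), class = c("chromosome_build",
                                            "data.frame"))
}

#' Write an AGP v2.1 file
#'
#' @param agp a `chromosome_build` (or AGP-shaped data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an AGP v2.1 file
#'
#' @param path AGP file.
#' @return data.frame with the same columns [build_chromosomes()] emits.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9))
    stop("malformed AGP row at line ", which(lengths(f) != 9)[1],
         call. = FALSE)
  m <- as.data.frame(t(vapply(f, identity, character(9))),
                     stringsAsFactors = FALSE)
  names(m) <- c("object", "object_beg", "object_end", "part_number",
                "component_type", "component_id", "component_beg",
                "component_end", "orientation")
  for (cc in c("object_beg", "object_end", "part_number"))
    m[[cc]] <- as.numeric(m[[cc]])
  structure(m, class = c("chromosome_build", "data.frame"))
}

#' Corrected scaffold part sequences
#'
#' Applies the curation to the scaffold sequences: chimeric scaffolds are
#' split at their breakpoints and minus-oriented parts are
#' reverse-complemented.
#'
#' @param seqs named character vector of scaffold sequences.
#' @param parts part table from [split_and_orient()].
#' @return named character vector of part sequences (names = part_id).
#' @export
corrected_scaffold_seqs <- function(seqs, parts) {
  out <- vapply(seq_len(nrow(parts)), function(i) {
    p <- parts[i, ]
    s <- substr(seqs[[p$scaffold_id]], p$start + 1, p$end)
    if (!is.na(p$orientation) && p$orientation == "-") revcomp(s) else s
  }, character(1))
  names(out) <- parts$part_id
  out
}

#' Composition string of each chromosome
#'
#' Parts in centromere-to-telomere order, each rendered as the scaffold id,
#' a probe-range suffix when the scaffold was split ("Sp<a>-<b>"), and
#' "rev" when reverse-oriented — e.g. "20p0-1rev 56rev 13rev".
#'
#' @param parts part table from [split_and_orient()].
#' @return named character vector, one composition string per chromosome.
#' @export
composition_strings <- function(parts) {
  parts <- parts[!is.na(parts$assigned_chromosome), , drop = FALSE]
  vapply(split(parts, parts$assigned_chromosome), function(p) {
    p <- p[order(p$order_on_chromosome), , drop = FALSE]
    lab <- paste0(p$part_id,
                  ifelse(!is.na(p$orientation) & p$orientation == "-",
                         "rev", ""))
    paste(lab, collapse = " ")
  }, character(1))
}

#' Number a karyotype and build the idiogram table
#'
#' Autosomes are numbered from acrocentric, then submetacentric, then
#' metacentric, within each morphology by decreasing relative length; the
#' sex chromosome keeps its label ("X") and is excluded from autosome
#' numbering. Length ties break by composition string (lexicographic),
#' which is reported via a message.
#'
#' @param idiogram data.frame with chromosome, relative_length, sd,
#'   morphology, composition (and optionally centromere_position).
#' @param sex_chromosome label of the sex chromosome in `chromosome`.
#' @return the idiogram data.frame ordered and with a `number` column
#'   ("1", "2", ..., sex label last).
#' @export
order_and_number <- function(idiogram, sex_chromosome = "X") {
  stopifnot(all(c("chromosome", "relative_length", "morphology") %in%
                  names(idiogram)))
  if (is.null(idiogram$composition)) idiogram$composition <- ""
  morder <- c(acrocentric = 1, submetacentric = 2, metacentric = 3)
  auto <- idiogram[idiogram$chromosome != sex_chromosome, , drop = FALSE]
  sex <- idiogram[idiogram$chromosome == sex_chromosome, , drop = FALSE]
  o <- order(morder[auto$morphology], -auto$relative_length,
             auto$composition)
  ties <- duplicated(paste(auto$morphology,
                           signif(auto$relative_length, 12)))
  if (any(ties))
    message("length ties broken by composition order for ",
            sum(ties), " chromosome(s)")
  auto <- auto[o, , drop = FALSE]
  auto$number <- as.character(seq_len(nrow(auto)))
  if (nrow(sex)) sex$number <- sex_chromosome
  out <- rbind(auto, sex)
  rownames(out) <- NULL
  out
}
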