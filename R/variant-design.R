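#' Define a barrier region
#'
#' A barrier region is a rigid structural segment that occludes the
#' substrate binding cleft — distinct from the flexible "lid" of classical
#' lipases. Regions are given in author residue numbering, inclusive at
#' both ends.
#'
#' @param label region label, e.g. `"D5"`.
#' @param start first residue (author numbering).
#' @param end last residue (inclusive).
#' @param chain chain identifier.
#' @return An object of class `BarrierRegion`.
#' @export
barrier_region <- function(label, start, end, chain = "A") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("region bounds must be integers")
  if (start > end) stop("region '", label, "': start > end")
  structure(list(label = label, chain = chain, start = start, end = end),
            class = "BarrierRegion")
}

#' Packaged barrier regions for the two BHET hydrolases
#'
#' The five candidate barrier segments per enzyme, in author numbering of
#' the parent structures. `bsest` spans D1 60-77, D2 105-112, D3 267-275,
#' D4 401-418, D5 410-418; `chrybhetase` spans D1 63-78, D2 66-76,
#' D3 267-274, D4 319-327, D5 368-376. D4/D5 of BsEst and D1/D2 of
#' ChryBHETase overlap by construction: nested candidates over the same
#' structural element are scored independently.
#'
#' @param enzyme `"bsest"` or `"chrybhetase"`.
#' @return list of [barrier_region()] objects.
#' @export
builtin_regions <- function(enzyme = c("bsest", "chrybhetase")) {
  enzyme <- match.arg(enzyme)
  tab <- switch(enzyme,
    bsest = list(c(60, 77), c(105, 112), c(267, 275), c(401, 418),
                 c(410, 418)),
    chrybhetase = list(c(63, 78), c(66, 76), c(267, 274), c(319, 327),
                       c(368, 376))
  )
  lapply(seq_along(tab), function(i) {
    barrier_region(paste0("D", i), tab[[i]][1], tab[[i]][2])
  })
}

#' Design a truncation variant
#'
#' Deletes the inclusive barrier region from the parent sequence and
#' bridges the junction with a flexible linker (Gly-Gly by default). The
#' variant is renumbered sequentially 1..N; the returned `number_map`
#' bridges old author numbers to new ones (deleted positions map to `NA`),
#' which is how the catalytic Ser is located after truncation.
#'
#' @param parent_seq one-letter parent sequence (single string).
#' @param region a [barrier_region()].
#' @param linker linker sequence inserted at the junction (default `"GG"`).
#' @param numbering author numbers parallel to `parent_seq`; defaults to
#'   `1:nchar(parent_seq)`.
#' @param parent_id parent identifier for bookkeeping.
#' @return An object of class `TruncationVariant` with fields `sequence`,
#'   `removed_count`, `number_map`, `region`, `linker`, `variant_id`.
#' @export
design_truncation <- function(parent_seq, region, linker = "GG",
                              numbering = NULL, parent_id = "parent") {
  stopifnot(inherits(region, "BarrierRegion"))
  chars <- strsplit(parent_seq, "")[[1]]
  n <- length(chars)
  if (is.null(numbering)) numbering <- seq_len(n)
  if (length(numbering) != n) stop("numbering must parallel the sequence")
  i1 <- match(region$start, numbering)
  i2 <- match(region$end, numbering)
  if (is.na(i1) || is.na(i2)) {
    stop("region '", region$label, "' (", region$start, "-", region$end,
         ") lies outside the parent numbering")
  }
  removed <- i2 - i1 + 1L
  link_chars <- if (nzchar(linker)) strsplit(linker, "")[[1]] else character(0)
  new_chars <- c(chars[seq_len(i1 - 1L)], link_chars,
                 if (i2 < n) chars[(i2 + 1L):n] else character(0))

  # sequential renumbering 1..N; retained parent positions keep order
  new_no <- rep(NA_integer_, n)
  if (i1 > 1L) new_no[seq_len(i1 - 1L)] <- seq_len(i1 - 1L)
  if (i2 < n) {
    shift <- length(link_chars) - removed
    new_no[(i2 + 1L):n] <- ((i2 + 1L):n) + shift
  }
  number_map <- data.frame(old = numbering, new = new_no)

  structure(list(
    variant_id = paste0(parent_id, "-", region$label),
    parent_id = parent_id,
    region = region,
    linker = linker,
    sequence = paste(new_chars, collapse = ""),
    removed_count = removed,
    number_map = number_map
  ), class = "TruncationVariant")
}

#' Design one variant per barrier region
#'
#' @param parent_seq one-letter parent sequence.
#' @param regions list of [barrier_region()] objects.
#' @param linker linker sequence.
#' @param numbering optional author numbering.
#' @param parent_id parent identifier.
#' @return list of `TruncationVariant` objects, one per region, in input
#'   order.
#' @export
batch_design <- function(parent_seq, regions, linker = "GG",
                         numbering = NULL, parent_id = "parent") {
  lapply(regions, function(r) {
    tryCatch(
      design_truncation(parent_seq, r, linker, numbering, parent_id),
      error = function(e) {
        stop("region '", r$label, "': ", conditionMessage(e), call. = FALSE)
      }
    )
  })
}

#' Map an old (parent) residue number to its number in the variant
#'
#' @param variant a `TruncationVariant`.
#' @param old_number author residue number in the parent.
#' @return new residue number, or `NA` for deleted positions.
#' @export
map_residue <- function(variant, old_number) {
  stopifnot(inherits(variant, "TruncationVariant"))
  i <- match(old_number, variant$number_map$old)
  if (is.na(i)) stop("residue ", old_number, " outside parent numbering")
  variant$number_map$new[i]
}

#' Write truncation variants to FASTA
#'
#' One record per variant with header `parent|label|start-end|linker`,
#' wrapped at 60 columns.
#'
#' @param variants list of `TruncationVariant` objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  if (length(variants) == 0L) {
    warning("no variants to write; creating empty file")
    file.create(path)
    return(invisible(path))
  }
  seqs <- lapply(variants, function(v) strsplit(v$sequence, "")[[1]])
  names(seqs) <- vapply(variants, function(v) {
    paste(v$parent_id, v$region$label,
          paste0(v$region$start, "-", v$region$end), v$linker, sep = "|")
  }, character(1))
  seqinr::write.fasta(seqs, names = names(seqs), file.out = path,
                      nbchar = 60)
  invisible(path)
}
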