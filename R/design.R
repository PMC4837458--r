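#' The designer-PPR scaffold
#'
#' A scaffold holds the 35-residue consensus repeat template (positions 5
#' and 35 are the programmable code slots; position 2 carries the
#' hydrophobic clamp valine and position 13 the phosphate-binding lysine)
#' plus the terminal capping domains fused to the repeat array to keep the
#' construct soluble. The packaged default is read from
#' `inst/extdata/scaffold_synthetic.txt`; the consensus-style sequences
#' there are synthetic stand-ins with the documented architecture (see the
#' file header) and can be replaced wholesale via `path`.
#'
#' @param path optional scaffold file; `NULL` loads the packaged default.
#'   The file dialect is `key<whitespace>sequence` with keys `template`,
#'   `ntd`, `ctd`; `#` comments and blank lines are ignored.
#' @return an object of class `ppr_scaffold` with fields `template` (35
#'   aa), `ntd`, `ctd`, `slot_positions` (5, 35) and `special_positions`
#' @export
default_scaffold <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scaffold_synthetic.txt", package = "pprkit",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("scaffold file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (length(tok) != 2L) {
      stop("line ", i, " of ", path, ": expected 'key sequence'", call. = FALSE)
    }
    kv[[tok[1]]] <- toupper(tok[2])
  }
  for (key in c("template", "ntd", "ctd")) {
    if (is.null(kv[[key]])) stop("scaffold file missing '", key, "'", call. = FALSE)
    bad <- setdiff(strsplit(kv[[key]], "")[[1]], AA1)
    if (length(bad)) {
      stop("scaffold '", key, "' contains non-amino-acid letters: ",
           paste(bad, collapse = ","), call. = FALSE)
    }
  }
  if (nchar(kv$template) != 35L) {
    stop("scaffold template must be exactly 35 residues, got ",
         nchar(kv$template), call. = FALSE)
  }
  structure(list(template = kv$template, ntd = kv$ntd, ctd = kv$ctd,
                 slot_positions = c(5L, 35L),
                 special_positions = c(clamp = 2L, lysine = 13L)),
            class = "ppr_scaffold")
}

#' @export
print.ppr_scaffold <- function(x, ...) {
  cat("<dPPR scaffold> template:", x$template, "\n")
  cat("  NTD:", nchar(x$ntd), "aa; CTD:", nchar(x$ctd),
      "aa; code slots at positions", paste(x$slot_positions, collapse = ", "), "\n")
  invisible(x)
}

# Validate and normalize an ssRNA target. Returns the uppercase U-form
# string; errors name the offending character and its 1-based position.
.normalize_target <- function(target_rna, allow_ambiguity = FALSE) {
  if (length(target_rna) != 1L || is.na(target_rna) || nchar(target_rna) == 0L) {
    stop("target RNA must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(target_rna), "")[[1]]
  if (any(chars == "T")) {
    warning("target contains T; treating as U (DNA-typed input tolerated)",
            call. = FALSE)
    chars[chars == "T"] <- "U"
  }
  allowed <- c(RNA_BASES, if (allow_ambiguity) "Y")
  bad <- which(!(chars %in% allowed))
  if (length(bad)) {
    stop("invalid base '", chars[bad[1]], "' at target position ", bad[1],
         ": expected A, C, G, U (or T)",
         if (!allow_ambiguity) "; IUPAC ambiguity codes are rejected (Y is allowed with allow_ambiguity = TRUE)",
         call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Design a dPPR protein for an ssRNA target
#'
#' Assembles the full designer construct: NTD cap, one code-programmed
#' 35-residue repeat per target nucleotide (repeat i reads nucleotide i;
#' N-to-C order matches 5'-to-3' order), then the CTD cap. By default each
#' repeat's positions 5 and 35 are set by the canonical design code for
#' its base (U:ND, C:NS, A:SN, G:TD); individual repeats can be overridden
#' with `codes`.
#'
#' @param target_rna the target, 5' to 3', over A/C/G/U (T tolerated and
#'   mapped to U). Lengths outside the advisory 2-30 repeat range warn.
#' @param scaffold a `ppr_scaffold`; default [default_scaffold()]
#' @param table a `ppr_code_table`; used only to annotate, overrides aside
#' @param codes optional per-repeat code overrides: a named character
#'   vector such as `c("5" = "NN", "6" = "NN")` mapping repeat index to a
#'   two-letter code
#' @param allow_ambiguity accept Y (pyrimidine) in the target, programmed
#'   with the degenerate code NN
#' @param offset integer added to the reported residue numbering of the
#'   annotation (0 keeps construct numbering starting at 1; 122 reproduces
#'   the crystal-construct numbering in which the ten repeats of the
#'   deposited structures occupy residues 174-523)
#' @return an object of class `dppr_design` with `full_sequence`, `ntd`,
#'   `ctd`, `target_rna` and a `repeats` annotation data frame (columns
#'   `repeat_index`, `code`, `target_base`, `start`, `end`; spans 1-based
#'   inclusive in the full sequence, shifted by `offset`)
#' @examples
#' d <- design_dppr("UUUUCCUUUU")
#' d$repeats$code   # ND,ND,ND,ND,NS,NS,ND,ND,ND,ND
#' @export
design_dppr <- function(target_rna, scaffold = default_scaffold(),
                        table = default_code_table(), codes = NULL,
                        allow_ambiguity = FALSE, offset = 0L) {
  stopifnot(inherits(scaffold, "ppr_scaffold"))
  target <- .normalize_target(target_rna, allow_ambiguity = allow_ambiguity)
  n <- nchar(target)
  if (n < 2L || n > 30L) {
    warning("target length ", n, " is outside the advisory 2-30 repeat range",
            call. = FALSE)
  }
  bases <- strsplit(target, "")[[1]]
  code_list <- vector("list", n)
  for (i in seq_len(n)) {
    key <- as.character(i)
    if (!is.null(codes) && key %in% names(codes)) {
      code_list[[i]] <- as_ppr_code(codes[[key]])
    } else if (bases[i] == "Y") {
      code_list[[i]] <- as_ppr_code("NN")
    } else {
      code_list[[i]] <- base_to_code(bases[i])
    }
  }
  repeat_seqs <- vapply(code_list, function(code) {
    s <- scaffold$template
    substr(s, 5L, 5L) <- code$pos5
    substr(s, 35L, 35L) <- code$pos35
    s
  }, character(1))
  full <- paste0(scaffold$ntd, paste(repeat_seqs, collapse = ""), scaffold$ctd)
  ntd_len <- nchar(scaffold$ntd)
  starts <- ntd_len + (seq_len(n) - 1L) * 35L + 1L
  annot <- data.frame(
    repeat_index = seq_len(n),
    code = vapply(code_list, format, character(1)),
    target_base = bases,
    start = starts + as.integer(offset),
    end = starts + 34L + as.integer(offset),
    stringsAsFactors = FALSE
  )
  structure(list(full_sequence = full, ntd = scaffold$ntd, ctd = scaffold$ctd,
                 repeats = annot, target_rna = target,
                 offset = as.integer(offset)),
            class = "dppr_design")
}

#' @export
print.dppr_design <- function(x, ...) {
  cat("<dPPR design> target 5'-", x$target_rna, "-3'  (",
      nrow(x$repeats), " repeats, ", nchar(x$full_sequence), " aa)\n", sep = "")
  cat("  codes:", paste(x$repeats$code, collapse = ","), "\n")
  invisible(x)
}

#' Write a design to FASTA and TSV annotation
#'
#' The FASTA record id is `dPPR_<target>`, its description carries the
#' target RNA verbatim, and the sequence is wrapped at 60 columns. The
#' annotation TSV has one row per repeat (`repeat_index`, `code`,
#' `target_base`, `start`, `end`) and round-trips through
#' [read_design_annot()].
#'
#' @param design a `dppr_design`
#' @param fasta_path output protein FASTA path
#' @param annot_path output TSV annotation path (optional)
#' @return invisibly, the paths written
#' @export
write_design <- function(design, fasta_path, annot_path = NULL) {
  stopifnot(inherits(design, "dppr_design"))
  seqs <- stats::setNames(design$full_sequence,
                          paste0("dPPR_", design$target_rna,
                                 " target=", design$target_rna))
  write_fasta(seqs, fasta_path, type = "protein")
  if (!is.null(annot_path)) {
    utils::write.table(design$repeats, annot_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta = fasta_path, annot = annot_path))
}

#' @rdname write_design
#' @param path an annotation TSV written by [write_design()]
#' @export
read_design_annot <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "character",
                                   "integer", "integer"))
}
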