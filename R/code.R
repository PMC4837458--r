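AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
RNA_BASES <- c("A", "C", "G", "U")

#' Construct a PPR code
#'
#' A PPR code is the pair of amino acids at repeat-internal positions 5 and
#' 35 of a 35-residue pentatricopeptide repeat. The pair determines which
#' RNA base the repeat recognizes: the canonical design codes are ND (U),
#' NS (C), SN (A) and TD (G), with degenerate codes NN (U/C), TN (A) and
#' SD (G) also supported.
#'
#' @param pos5 one-letter amino acid at repeat position 5
#' @param pos35 one-letter amino acid at repeat position 35
#' @return an object of class `ppr_code`
#' @examples
#' ppr_code("N", "D")   # recognizes uracil
#' as_ppr_code("TD")    # recognizes guanine
#' @export
ppr_code <- function(pos5, pos35) {
  pos5 <- toupper(as.character(pos5))
  pos35 <- toupper(as.character(pos35))
  for (aa in c(pos5, pos35)) {
    if (length(aa) != 1L || nchar(aa) != 1L || !(aa %in% AA1)) {
      stop("PPR code residues must be single letters from the 20-letter amino-acid alphabet, got '",
           aa, "'", call. = FALSE)
    }
  }
  structure(list(pos5 = pos5, pos35 = pos35), class = "ppr_code")
}

#' @rdname ppr_code
#' @param x a `ppr_code`, or a two-letter string such as `"ND"`
#' @export
as_ppr_code <- function(x) {
  if (inherits(x, "ppr_code")) return(x)
  x <- as.character(x)
  if (length(x) == 1L && nchar(x) == 2L) {
    return(ppr_code(substr(x, 1, 1), substr(x, 2, 2)))
  }
  if (length(x) == 2L) return(ppr_code(x[1], x[2]))
  stop("cannot interpret '", paste(x, collapse = ""), "' as a PPR code", call. = FALSE)
}

#' @export
format.ppr_code <- function(x, ...) paste0(x$pos5, x$pos35)

#' @export
print.ppr_code <- function(x, ...) {
  cat("<PPR code>", format(x), "\n")
  invisible(x)
}

#' Construct a base probability profile
#'
#' @param A,C,G,U probabilities over the four RNA bases; must be
#'   non-negative and sum to 1 (within 1e-9)
#' @return a named numeric vector of class `base_profile`
#' @export
base_profile <- function(A, C, G, U) {
  p <- c(A = A, C = C, G = G, U = U)
  if (any(p < 0)) stop("base probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("base probabilities must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  }
  structure(p, class = c("base_profile", "numeric"))
}

#' Bases attaining the maximum probability of a profile
#'
#' Degenerate codes (e.g. NN) yield more than one base.
#'
#' @param profile a `base_profile`
#' @param tol ties closer than this are grouped
#' @return character vector of base letters
#' @export
profile_argmax <- function(profile, tol = 1e-9) {
  names(profile)[profile >= max(profile) - tol]
}

# Build one exact-code profile: `mass` split equally over the specified
# bases, remainder spread uniformly over the others.
.specific_profile <- function(bases, mass) {
  p <- stats::setNames(rep((1 - mass) / (4 - length(bases)), 4), RNA_BASES)
  p[bases] <- mass / length(bases)
  do.call(base_profile, as.list(p))
}

#' The default PPR code table
#'
#' Contains the four canonical design codes (ND, NS, SN, TD recognizing
#' U, C, A, G) and the three degenerate codes delineated from the complex
#' structures (NN for U/C, TN for A, SD for G). Codes without an exact
#' entry fall back on position-5 chemistry: asparagine at position 5
#' prefers pyrimidines, serine/threonine prefer purines, and small
#' residues (A/G) admit purines with little specificity. Anything else is
#' scored uniform.
#'
#' @param specificity_mass probability mass placed on the specified base
#'   set of an exact code (default 0.90); the remainder is spread
#'   uniformly over the other bases
#' @return an object of class `ppr_code_table`
#' @export
default_code_table <- function(specificity_mass = 0.90) {
  stopifnot(specificity_mass > 0, specificity_mass <= 1)
  entries <- list(
    ND = .specific_profile("U", specificity_mass),
    NS = .specific_profile("C", specificity_mass),
    SN = .specific_profile("A", specificity_mass),
    TD = .specific_profile("G", specificity_mass),
    NN = .specific_profile(c("U", "C"), specificity_mass),
    TN = .specific_profile("A", specificity_mass),
    SD = .specific_profile("G", specificity_mass)
  )
  fallback <- list(
    pyrimidine = base_profile(A = 0.15, C = 0.35, G = 0.15, U = 0.35),
    purine     = base_profile(A = 0.35, C = 0.15, G = 0.35, U = 0.15),
    small      = base_profile(A = 0.30, C = 0.20, G = 0.30, U = 0.20)
  )
  structure(list(entries = entries, fallback = fallback,
                 specificity_mass = specificity_mass),
            class = "ppr_code_table")
}

#' @export
print.ppr_code_table <- function(x, ...) {
  cat("<PPR code table>", length(x$entries), "exact codes, specificity mass",
      x$specificity_mass, "\n")
  for (code in names(x$entries)) {
    cat(sprintf("  %s -> %s\n", code,
                paste(profile_argmax(x$entries[[code]]), collapse = "/")))
  }
  invisible(x)
}

#' Canonical design code for an RNA base
#'
#' Returns the PPR code used when programming a designer repeat to read a
#' given base: U maps to ND, C to NS, A to SN and G to TD. DNA-style T is
#' accepted and treated as U.
#'
#' @param base a single RNA base letter (A, C, G, U; T tolerated)
#' @return a `ppr_code`
#' @export
base_to_code <- function(base) {
  base <- toupper(as.character(base))
  if (length(base) != 1L || nchar(base) != 1L) {
    stop("base_to_code() expects a single base letter", call. = FALSE)
  }
  if (base == "T") base <- "U"
  switch(base,
    U = ppr_code("N", "D"),
    C = ppr_code("N", "S"),
    A = ppr_code("S", "N"),
    G = ppr_code("T", "D"),
    stop("invalid RNA base '", base, "': expected one of A, C, G, U (or T)",
         call. = FALSE)
  )
}

#' Base-preference profile of a PPR code
#'
#' Exact table entries take precedence. Otherwise the position-5 residue
#' decides a fallback: N at 5 weights pyrimidines, S/T at 5 weight purines,
#' and A/G at 5 give a weak purine tilt (small side chains accommodate
#' purines without steric clash but confer little specificity). Any other
#' combination scores uniform. This is a total function over valid codes.
#'
#' @param code a `ppr_code` or two-letter string
#' @param table a `ppr_code_table`; defaults to [default_code_table()]
#' @return a `base_profile` summing to 1
#' @export
code_to_profile <- function(code, table = default_code_table()) {
  code <- as_ppr_code(code)
  stopifnot(inherits(table, "ppr_code_table"))
  key <- format(code)
  if (!is.null(table$entries[[key]])) return(table$entries[[key]])
  if (code$pos5 == "N") return(table$fallback$pyrimidine)
  if (code$pos5 %in% c("S", "T")) return(table$fallback$purine)
  if (code$pos5 %in% c("A", "G")) return(table$fallback$small)
  base_profile(0.25, 0.25, 0.25, 0.25)
}

#' Load a PPR code table from a config file
#'
#' The file format is plain text: one entry per line, whitespace-separated,
#' `CODE pA pC pG pU` (probabilities over A, C, G, U summing to 1). Lines
#' starting with `#` and blank lines are ignored. A line
#' `specificity_mass VALUE` resets the mass used for the built-in default
#' entries. File entries override the packaged defaults; codes absent from
#' the file keep their default or fallback behaviour.
#'
#' @param path path to the config file, or `NULL` for the packaged default
#' @return a `ppr_code_table`
#' @export
load_code_table <- function(path = NULL) {
  if (is.null(path)) return(default_code_table())
  if (!file.exists(path)) stop("code table file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  mass <- 0.90
  overrides <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (identical(tok[1], "specificity_mass")) {
      mass <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(mass) || mass <= 0 || mass > 1) {
        stop("line ", i, " of ", path, ": invalid specificity_mass '", tok[2], "'",
             call. = FALSE)
      }
      next
    }
    if (length(tok) != 5L) {
      stop("line ", i, " of ", path, ": expected 'CODE pA pC pG pU', got: ", ln,
           call. = FALSE)
    }
    p <- suppressWarnings(as.numeric(tok[2:5]))
    if (anyNA(p)) {
      stop("line ", i, " of ", path, ": non-numeric probability in: ", ln,
           call. = FALSE)
    }
    code <- format(as_ppr_code(tok[1]))
    prof <- tryCatch(base_profile(p[1], p[2], p[3], p[4]), error = function(e) {
      stop("line ", i, " of ", path, ": ", conditionMessage(e), call. = FALSE)
    })
    overrides[[code]] <- prof
  }
  table <- default_code_table(specificity_mass = mass)
  for (code in names(overrides)) table$entries[[code]] <- overrides[[code]]
  table
}
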