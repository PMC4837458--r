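#' Read sequences from FASTA
#'
#' Returns a named character vector of uppercase sequences. Nucleotide
#' records ("rna" type) have T normalized to U with a warning. Duplicate
#' record ids warn; an empty file errors.
#'
#' @param path FASTA file
#' @param type `"auto"` (no normalization), `"protein"`, `"rna"` or
#'   `"dna"`
#' @return named character vector (names are the full header lines up to
#'   the first space by Biostrings convention, kept verbatim)
#' @export
read_fasta <- function(path, type = c("auto", "protein", "rna", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- names(set)
  if (anyDuplicated(ids)) {
    warning("duplicate record ids in ", path, call. = FALSE)
  }
  if (type == "rna" && any(grepl("T", seqs, fixed = TRUE))) {
    warning("RNA record(s) contain T; normalized to U", call. = FALSE)
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
  }
  stats::setNames(seqs, ids)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences
#' @param width line-wrap width (default 60)
#' @export
write_fasta <- function(seqs, path, type = c("auto", "protein", "rna", "dna"),
                        width = 60L) {
  type <- match.arg(type)
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Generate an ideal superhelix fixture
#'
#' Places repeat centroids on a mathematically exact helix of known rise,
#' twist and radius, then (optionally) surrounds each centroid with
#' `atoms_per_repeat` seeded jitter atoms whose mean is re-centred onto
#' the exact helical point, so the ground-truth parameters are preserved
#' no matter the jitter. Positive twist with the axis oriented along
#' increasing repeat index gives a right-handed helix. Used as the oracle
#' generator for the superhelix fitter.
#'
#' @param rise axial rise per repeat in Angstrom
#' @param twist_deg twist per repeat in degrees (sign sets handedness)
#' @param radius helix radius in Angstrom
#' @param n_repeats number of repeats (at least 4)
#' @param atoms_per_repeat C-alpha atoms per repeat (default 1)
#' @param jitter_sd jitter spread in Angstrom (default 0.5 when
#'   `atoms_per_repeat` > 1)
#' @param seed RNG seed; identical seeds give identical coordinates
#' @return list with `model` (a `structure_model` of C-alpha atoms),
#'   `segmentation` (data frame usable by [superhelix()]) and `truth`
#'   (rise, twist, radius, period, handedness)
#' @export
make_ideal_helix <- function(rise, twist_deg, radius, n_repeats,
                             atoms_per_repeat = 1L, jitter_sd = 0.5,
                             seed = NULL) {
  if (rise <= 0 || radius <= 0) {
    stop("rise and radius must be positive", call. = FALSE)
  }
  if (n_repeats < 4L) {
    stop("superhelix fitting needs at least 4 repeats", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  theta <- (seq_len(n_repeats) - 1L) * twist_deg * pi / 180
  cen <- cbind(radius * cos(theta), radius * sin(theta),
               (seq_len(n_repeats) - 1L) * rise)
  rows <- list()
  for (i in seq_len(n_repeats)) {
    k <- as.integer(atoms_per_repeat)
    pts <- matrix(rep(cen[i, ], each = k), nrow = k)
    if (k > 1L) {
      jit <- matrix(stats::rnorm(3L * k, sd = jitter_sd), ncol = 3)
      jit <- sweep(jit, 2, colMeans(jit))  # re-centre: centroid stays exact
      pts <- pts + jit
    }
    rows[[i]] <- data.frame(
      chain = "A", resno = (i - 1L) * k + seq_len(k), resname = "ALA",
      atom = "CA", element = "C", altloc = " ",
      x = pts[, 1], y = pts[, 2], z = pts[, 3], occ = 1,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  model <- .new_structure_model(atoms, source = "ideal_helix")
  k <- as.integer(atoms_per_repeat)
  segmentation <- data.frame(
    repeat_index = seq_len(n_repeats),
    start_res = (seq_len(n_repeats) - 1L) * k + 1L,
    end_res = seq_len(n_repeats) * k
  )
  attr(segmentation, "chain") <- "A"
  list(model = model, segmentation = segmentation,
       truth = list(rise = rise, twist = twist_deg, radius = radius,
                    period = abs(rise * 360 / twist_deg),
                    handedness = if (twist_deg >= 0) "right" else "left"))
}

#' Run configuration
#'
#' Central container for the tunable cutoffs and the seed, validated on
#' construction. `read_config()` loads the same fields from a plain-text
#' `key value` file (comments `#`, unknown keys error).
#'
#' @param code_table_path,scaffold_path optional config-file overrides
#' @param hbond_cutoff,salt_cutoff,val2_cutoff distance cutoffs (Angstrom)
#' @param scan_threshold repeat-scanner threshold fraction
#' @param seed non-negative integer seed
#' @param verbose logical
#' @return an object of class `ppr_config`
#' @export
run_config <- function(code_table_path = NULL, scaffold_path = NULL,
                       hbond_cutoff = 3.5, salt_cutoff = 4.0,
                       val2_cutoff = 4.5, scan_threshold = 0.6,
                       seed = 0L, verbose = FALSE) {
  for (val in c(hbond_cutoff, salt_cutoff, val2_cutoff, scan_threshold)) {
    if (!is.numeric(val) || val <= 0) {
      stop("cutoffs and threshold must be positive numbers", call. = FALSE)
    }
  }
  if (!is.numeric(seed) || seed < 0 || seed != floor(seed)) {
    stop("seed must be a non-negative integer", call. = FALSE)
  }
  structure(list(code_table_path = code_table_path,
                 scaffold_path = scaffold_path,
                 hbond_cutoff = hbond_cutoff, salt_cutoff = salt_cutoff,
                 val2_cutoff = val2_cutoff, scan_threshold = scan_threshold,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "ppr_config")
}

#' @rdname run_config
#' @param path config file path
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  args <- list()
  numeric_keys <- c("hbond_cutoff", "salt_cutoff", "val2_cutoff",
                    "scan_threshold", "seed")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (length(tok) != 2L) {
      stop("line ", i, " of ", path, ": expected 'key value'", call. = FALSE)
    }
    key <- tok[1]
    if (!key %in% c(numeric_keys, "code_table_path", "scaffold_path",
                    "verbose")) {
      stop("line ", i, " of ", path, ": unknown config key '", key, "'",
           call. = FALSE)
    }
    args[[key]] <- if (key %in% numeric_keys) {
      v <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(v)) stop("line ", i, " of ", path, ": '", key,
                         "' must be numeric", call. = FALSE)
      v
    } else if (key == "verbose") tolower(tok[2]) %in% c("true", "1", "yes")
    else tok[2]
  }
  do.call(run_config, args)
}

#' Fetch a deposited structure from the PDB
#'
#' Downloads `<id>.pdb` from RCSB into `dir` (skipping the download when a
#' cached copy exists) and parses it. Requires network access; analyses of
#' the deposited designer-complex coordinates are optional extras on top
#' of the offline fixture-based test surface.
#'
#' @param pdb_id four-character PDB accession, e.g. `"5I9G"`
#' @param dir cache directory
#' @param quiet passed to [utils::download.file()]
#' @return a `structure_model`
#' @export
fetch_structure <- function(pdb_id, dir = tempdir(), quiet = TRUE) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", pdb_id))
  dest <- file.path(dir, paste0(toupper(pdb_id), ".pdb"))
  if (!file.exists(dest)) {
    url <- paste0("https://files.rcsb.org/download/", toupper(pdb_id), ".pdb")
    ok <- tryCatch(utils::download.file(url, dest, quiet = quiet) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(dest)) {
      if (file.exists(dest)) unlink(dest)
      stop("could not download ", pdb_id, " from RCSB (offline?)", call. = FALSE)
    }
  }
  read_structure(dest, format = "pdb")
}
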