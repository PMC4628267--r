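## ---- subfamily-structured family simulator ----------------------------------

#' Define a synthetic protein family with conserved subfamilies
#'
#' The model lays columns out in repeating units of functional classes:
#'
#' * `family`: one residue conserved across every subfamily,
#' * `shared signature`: every subfamily conserved, each at a distinct
#'   residue (the columns that separate all subfamilies, and the sites where
#'   switch-of-function variants are planted),
#' * `cof`: conserved at a common residue in every subfamily except the
#'   target one, where the site is unconstrained (the sites where
#'   conservation-of-function variants are planted),
#' * `private signature`: conserved in exactly one non-target subfamily
#'   (gain-of-function sites), and
#' * `variable`: unconstrained everywhere.
#'
#' The `"full"` layout cycles through all five classes; the `"signature"`
#' layout alternates family and shared-signature columns only, so that at
#' conservation 1 all rows of a subfamily are identical (used for clustering
#' benchmarks; gain and conservation variants cannot be planted on it).
#'
#' @param n_subfamilies number of subfamilies (>= 1; >= 2 for gain/switch
#'   plants).
#' @param rows_per_subfamily sequences per subfamily.
#' @param width alignment columns.
#' @param conservation per-column probability that a row carries its
#'   subfamily's consensus at a constrained column; in \[0, 1\].
#' @param layout `"full"` or `"signature"`.
#' @param seed integer seed; consensus residues and sequence draws are both
#'   deterministic given the seed.
#' @return an object of class `family_model`, including
#'   `family_conserved_columns`, `subfamily_signature_columns` (per
#'   subfamily: shared plus privately owned signature columns),
#'   `cof_columns`, `variable_columns`, the per-subfamily `consensus` matrix
#'   (NA = unconstrained) and the canonical `query_residues`.
#' @export
family_model <- function(n_subfamilies = 3L, rows_per_subfamily = 12L,
                         width = 40L, conservation = 0.95,
                         layout = c("full", "signature"), seed = 1L) {
  layout <- match.arg(layout)
  n <- as.integer(n_subfamilies)
  if (n < 1L) stop("need at least one subfamily")
  if (rows_per_subfamily < 1L) stop("rows_per_subfamily must be >= 1")
  if (conservation < 0 || conservation > 1) stop("conservation must be in [0, 1]")
  min_width <- if (layout == "full") 5L else 2L
  if (width < min_width) {
    stop("width too small to hold the conserved and signature column classes")
  }

  classes <- character(width)
  owner <- rep(NA_integer_, width)
  for (col in seq_len(width)) {
    if (layout == "signature") {
      classes[col] <- if ((col - 1L) %% 2L == 0L) "family" else "shared"
    } else {
      r <- (col - 1L) %% 5L
      classes[col] <- c("family", "shared", "cof", "private", "variable")[r + 1L]
      if (classes[col] == "private") {
        if (n < 2L) { classes[col] <- "variable" } else {
          owner[col] <- ((col - 1L) %/% 5L) %% (n - 1L) + 2L  # subfamily 2..n
        }
      }
      if (classes[col] == "cof" && n < 2L) classes[col] <- "variable"
    }
  }

  consensus <- matrix(NA_character_, n, width)
  query_residues <- rep(NA_character_, width)
  with_seed(seed, {
    for (col in seq_len(width)) {
      switch(classes[col],
        family = {
          consensus[, col] <- sample(AA_ALPHABET20, 1L)
          query_residues[col] <- consensus[1L, col]
        },
        shared = {
          consensus[, col] <- sample(AA_ALPHABET20, n)
          query_residues[col] <- consensus[1L, col]
        },
        cof = {
          rc <- sample(AA_ALPHABET20, 1L)
          consensus[-1L, col] <- rc
          query_residues[col] <- rc
        },
        private = {
          rs <- sample(AA_ALPHABET20, 1L)
          consensus[owner[col], col] <- rs
          query_residues[col] <- sample(setdiff(AA_ALPHABET20, rs), 1L)
        },
        variable = NULL)
    }
  })

  sig <- lapply(seq_len(n), function(s) {
    sort(c(which(classes == "shared"),
           which(classes == "private" & !is.na(owner) & owner == s)))
  })
  structure(list(
    n_subfamilies = n, rows_per_subfamily = as.integer(rows_per_subfamily),
    width = as.integer(width), conservation = conservation,
    layout = layout, seed = as.integer(seed),
    column_class = classes, owner = owner, consensus = consensus,
    query_residues = query_residues,
    family_conserved_columns = which(classes == "family"),
    subfamily_signature_columns = sig,
    cof_columns = which(classes == "cof"),
    variable_columns = which(classes == "variable")
  ), class = "family_model")
}

#' @export
print.family_model <- function(x, ...) {
  cat(sprintf("family_model: %d subfamilies x %d rows, %d columns, conservation %.2f (%s layout)\n",
              x$n_subfamilies, x$rows_per_subfamily, x$width, x$conservation, x$layout))
  invisible(x)
}

#' Simulate an aligned family from a model
#'
#' Each row draws, per column, its subfamily's consensus residue with
#' probability `conservation` and a uniform different residue otherwise;
#' unconstrained columns draw uniformly over all 20 residues. The query is
#' the first row of subfamily 0 and carries the model's canonical wild-type
#' residues: its own subfamily's consensus at constrained columns, and the
#' model's fixed canonical state at cof and private-signature columns
#' (where its subfamily is unconstrained). A reference wild-type sequence
#' is the functional representative of its subfamily, not a random draw;
#' unconstrained variable columns stay random.
#'
#' @param model a [family_model()].
#' @return an object of class `sim_family`: list with `msa` (an [aa_msa()],
#'   query in row 1), `truth` (named subfamily labels, target subfamily 0)
#'   and `model`.
#' @export
simulate_family <- function(model) {
  stopifnot(inherits(model, "family_model"))
  n <- model$n_subfamilies; m <- model$rows_per_subfamily; w <- model$width
  ids <- unlist(lapply(seq_len(n), function(s) {
    sprintf("sf%d_%d", s - 1L, seq_len(m))
  }))
  mat <- matrix(NA_character_, n * m, w, dimnames = list(ids, NULL))
  with_seed(model$seed, {
    for (s in seq_len(n)) {
      for (i in seq_len(m)) {
        row <- (s - 1L) * m + i
        for (col in seq_len(w)) {
          cons <- model$consensus[s, col]
          mat[row, col] <- if (!is.na(cons)) {
            if (stats::runif(1L) < model$conservation) cons
            else sample(setdiff(AA_ALPHABET20, cons), 1L)
          } else {
            sample(AA_ALPHABET20, 1L)
          }
        }
      }
    }
  })
  forced <- which(!is.na(model$query_residues))
  mat[1L, forced] <- model$query_residues[forced]
  truth <- rep(seq_len(n) - 1L, each = m)
  names(truth) <- ids
  structure(list(msa = aa_msa(mat, query = 1L), truth = truth, model = model),
            class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("sim_family: %d sequences x %d columns (%d subfamilies)\n",
              nrow(x$msa$mat), ncol(x$msa$mat), x$model$n_subfamilies))
  invisible(x)
}

#' Plant a variant of a requested functional-outcome type
#'
#' Chooses a site on the query sequence whose conservation context should
#' produce the requested classification:
#'
#' * `LoF`: a family-conserved column, mutated to a residue absent from the
#'   whole column (the mutant fits no subfamily);
#' * `SoF`: a shared signature column, mutated from the target subfamily's
#'   residue to another subfamily's aligned signature residue;
#' * `GoF`: a private signature column of a non-target subfamily — a site
#'   unconstrained in the target subfamily — mutated to that subfamily's
#'   signature residue;
#' * `CoF`: a cof column — conserved at the query's residue in every
#'   non-target subfamily, unconstrained in the target — mutated to a
#'   residue absent from the column, so the mutant neither loses target fit
#'   nor moves toward another subfamily.
#'
#' The middle-most qualifying column is used, so the planted site is
#' deterministic given the simulated family.
#'
#' @param fam a [simulate_family()] result.
#' @param kind `"LoF"`, `"GoF"`, `"SoF"` or `"CoF"`.
#' @return list with `variant` (a [parse_variant()] spec on the ungapped
#'   query), `expected` (the planted label) and `column` (alignment column).
#' @export
plant_variant <- function(fam, kind = c("LoF", "GoF", "SoF", "CoF")) {
  stopifnot(inherits(fam, "sim_family"))
  kind <- match.arg(kind)
  model <- fam$model
  mat <- fam$msa$mat
  qrow <- mat[1L, ]
  if (kind %in% c("GoF", "SoF") && model$n_subfamilies < 2L) {
    stop("cannot plant a ", kind, " variant: need at least 2 subfamilies")
  }
  absent_residue <- function(col, not = character(0)) {
    free <- setdiff(AA_ALPHABET20, c(unique(mat[, col]), not))
    if (length(free) == 0L) NA_character_ else free[1L]
  }
  cands <- switch(kind,
    LoF = {
      cols <- model$family_conserved_columns
      cols[qrow[cols] == model$consensus[1L, cols] &
             !is.na(vapply(cols, absent_residue, character(1)))]
    },
    SoF = {
      cols <- which(model$column_class == "shared")
      cols[qrow[cols] == model$consensus[1L, cols]]
    },
    GoF = {
      cols <- which(model$column_class == "private")
      cols[qrow[cols] != model$consensus[cbind(model$owner[cols], cols)]]
    },
    CoF = {
      cols <- model$cof_columns
      cols[!is.na(vapply(cols, absent_residue, character(1)))]
    })
  if (length(cands) == 0L) {
    stop("cannot plant a ", kind, " variant under this model geometry")
  }
  col <- cands[ceiling(length(cands) / 2)]
  wt <- qrow[col]
  mut <- switch(kind,
    LoF = absent_residue(col, not = wt),
    SoF = model$consensus[2L, col],
    GoF = model$consensus[model$owner[col], col],
    CoF = absent_residue(col, not = wt))
  position <- sum(qrow[seq_len(col)] != GAP_CHAR)
  list(variant = parse_variant(wt = wt, position = position, mut = mut),
       expected = kind, column = col)
}

#' Write a simulated family to disk
#'
#' Writes the aligned FASTA, the ground-truth subfamily map, and optionally
#' a table of planted variants with their expected labels.
#'
#' @param fam a [simulate_family()] result.
#' @param dir output directory (created if needed).
#' @param variants optional list of [plant_variant()] results.
#' @return the directory path, invisibly.
#' @export
write_family <- function(fam, dir, variants = NULL) {
  stopifnot(inherits(fam, "sim_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(fam$msa, file.path(dir, "family.fasta"))
  write.table(data.frame(id = names(fam$truth), subfamily = fam$truth),
              file.path(dir, "subfamilies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(variants)) {
    df <- data.frame(
      variant = vapply(variants, function(v) format(v$variant), character(1)),
      expected = vapply(variants, function(v) v$expected, character(1)),
      column = vapply(variants, function(v) v$column, numeric(1)))
    write.table(df, file.path(dir, "variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
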