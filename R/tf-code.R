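#' Combinatorial transcription-factor code
#'
#' The minimal transcription-factor combination that specifies T4/T5
#' subtype identity: a Dac/Ab-class flag (subtypes a,b), an Omb/Pros-class
#' flag (subtypes c,d) and a Grain flag (subtypes b,c). The two class
#' flags are mutually exclusive (Omb represses Dac), so exactly one must
#' be set.
#'
#' @param class_ab Logical: Dac/Ab-class expression.
#' @param class_cd Logical: Omb/Pros-class expression.
#' @param grain Logical: Grain expression.
#' @return Object of class `tf_code`.
#' @export
tf_code <- function(class_ab, class_cd, grain) {
  stopifnot(is.logical(class_ab), is.logical(class_cd), is.logical(grain))
  if (class_ab == class_cd) {
    stop("invalid code: exactly one of class_ab, class_cd must be TRUE",
         call. = FALSE)
  }
  structure(list(class_ab = class_ab, class_cd = class_cd, grain = grain),
            class = "tf_code")
}

#' @export
print.tf_code <- function(x, ...) {
  cat(sprintf("tf_code: %s / Grain%s -> subtype %s\n",
              if (x$class_ab) "Dac+/Ab+" else "Omb+/Pros+",
              if (x$grain) "+" else "-", decode_tf_code(x)))
  invisible(x)
}

#' Decode a transcription-factor code to a subtype
#'
#' Dac/Ab without Grain is subtype a; Dac/Ab with Grain is b; Omb/Pros
#' with Grain is c; Omb/Pros without Grain is d.
#'
#' @param code A [tf_code].
#' @return One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @export
decode_tf_code <- function(code) {
  stopifnot(inherits(code, "tf_code"))
  if (code$class_ab == code$class_cd) stop("invalid code", call. = FALSE)
  if (code$class_ab) {
    if (code$grain) "b" else "a"
  } else {
    if (code$grain) "c" else "d"
  }
}

#' Encode a subtype as its transcription-factor code
#'
#' Exact inverse of [decode_tf_code].
#'
#' @param subtype One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @return A [tf_code].
#' @export
encode_subtype <- function(subtype) {
  switch(as.character(subtype),
         a = tf_code(TRUE, FALSE, FALSE),
         b = tf_code(TRUE, FALSE, TRUE),
         c = tf_code(FALSE, TRUE, TRUE),
         d = tf_code(FALSE, TRUE, FALSE),
         stop("unknown subtype: ", subtype, call. = FALSE))
}

#' Apply a Grain perturbation to a code
#'
#' Overexpression sets the Grain flag (converting a to b and d to c);
#' knockdown clears it (converting b to a and c to d). The class flags
#' never change, so perturbations move identity only within the (a,b)
#' and (c,d) pairs.
#'
#' @param code A [tf_code].
#' @param mode `"overexpression"`, `"knockdown"` or `"none"`.
#' @return The perturbed [tf_code].
#' @export
perturb_code <- function(code, mode = c("none", "overexpression",
                                        "knockdown")) {
  stopifnot(inherits(code, "tf_code"))
  mode <- match.arg(mode)
  if (mode == "overexpression") code$grain <- TRUE
  if (mode == "knockdown") code$grain <- FALSE
  code
}

#' Grain cell-body enrichment score
#'
#' For each subtype within each optic-lobe group: the mean Grain
#' fluorescence of that subtype's cell bodies divided by the mean
#' fluorescence of the Lim1-negative (non-T4/T5) cell bodies of the same
#' group. Subtype membership of each Lim1-positive cell body follows the
#' marker logic: Dac marks subtypes a,b and the b,c reporter (grain-Gal4)
#' marks subtypes b,c, so the two stains jointly separate a, b, c and d.
#' The score is invariant under global rescaling of all intensities.
#'
#' @param cellbody_table data.frame with columns `mean_intensity`,
#'   `lim1_positive`, `dac_positive`, `gal4_positive` and optionally
#'   `optic_lobe` (one group is assumed when absent).
#' @param min_background Minimum number of Lim1-negative cell bodies
#'   required per group (default 10).
#' @return data.frame with columns `optic_lobe`, `subtype`, `score`,
#'   `n_cells`.
#' @export
grain_score <- function(cellbody_table, min_background = 10) {
  need <- c("mean_intensity", "lim1_positive", "dac_positive",
            "gal4_positive")
  if (!all(need %in% names(cellbody_table))) {
    stop("cell-body table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tb <- cellbody_table
  if (is.null(tb$optic_lobe)) tb$optic_lobe <- "lobe1"
  out <- list()
  for (g in unique(tb$optic_lobe)) {
    sub <- tb[tb$optic_lobe == g, ]
    bg <- sub[!sub$lim1_positive, ]
    if (nrow(bg) < min_background) {
      stop("fewer than ", min_background,
           " Lim1-negative background cell bodies in group ", g,
           call. = FALSE)
    }
    bg_mean <- mean(bg$mean_intensity)
    pos <- sub[sub$lim1_positive, ]
    st <- ifelse(pos$dac_positive,
                 ifelse(pos$gal4_positive, "b", "a"),
                 ifelse(pos$gal4_positive, "c", "d"))
    for (s in c("a", "b", "c", "d")) {
      cells <- pos$mean_intensity[st == s]
      if (!length(cells)) next
      out[[length(out) + 1L]] <- data.frame(
        optic_lobe = g, subtype = s,
        score = mean(cells) / bg_mean, n_cells = length(cells))
    }
  }
  if (!length(out)) stop("no Lim1-positive cell bodies in table", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
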