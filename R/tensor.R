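#' Four-way postprandial response tensor
#'
#' The central data container: a complete four-way array of metabolite
#' responses indexed (metabolite, time, individual, diet).  Time is an ordinal
#' index; by convention the first time point is the pre-meal baseline sample.
#' Every preprocessing step appends a tag to `preprocessing_log`, so a
#' processed tensor can be reproduced bit-for-bit from the raw data with
#' [replay_preprocessing()].
#'
#' @param values numeric four-way array, dimensions M x T x I x D.
#' @param metabolite_ids,individual_ids,diet_ids axis labels; defaults are
#'   generated (`m1..`, `i1..`, `d1..`).
#' @param time_points ordinal time labels, default `0:(T-1)` (0 = baseline).
#' @param preprocessing_log character vector of applied-transform tags.
#' @return An object of class `response_tensor`.
#' @seealso [read_tensor_long()], [subtract_baseline()],
#'   [standardize_per_diet()], [filter_low_variance()],
#'   [downsample_logarithmic()]
#' @export
response_tensor <- function(values, metabolite_ids = NULL, time_points = NULL,
                            individual_ids = NULL, diet_ids = NULL,
                            preprocessing_log = character()) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stopf("`values` must be a four-way array (metabolite x time x individual x diet)")
  dm <- dim(values)
  if (any(dm < 1L)) stopf("all tensor dimensions must be >= 1")
  if (anyNA(values) || any(!is.finite(values)))
    stopf("tensor contains missing or non-finite values")
  metabolite_ids <- as.character(metabolite_ids %||% paste0("m", seq_len(dm[1])))
  time_points <- as.numeric(time_points %||% (seq_len(dm[2]) - 1))
  individual_ids <- as.character(individual_ids %||% paste0("i", seq_len(dm[3])))
  diet_ids <- as.character(diet_ids %||% paste0("d", seq_len(dm[4])))
  lens <- c(length(metabolite_ids), length(time_points),
            length(individual_ids), length(diet_ids))
  if (!identical(as.integer(lens), as.integer(dm)))
    stopf("axis label lengths (%s) do not match tensor dimensions (%s)",
          paste(lens, collapse = ","), paste(dm, collapse = ","))
  dimnames(values) <- list(metabolite_ids, as.character(time_points),
                           individual_ids, diet_ids)
  structure(
    list(values = values, metabolite_ids = metabolite_ids,
         time_points = time_points, individual_ids = individual_ids,
         diet_ids = diet_ids, preprocessing_log = as.character(preprocessing_log)),
    class = "response_tensor")
}

#' @export
dim.response_tensor <- function(x) dim(x$values)

#' @export
print.response_tensor <- function(x, ...) {
  dm <- dim(x)
  cat(sprintf("<response_tensor> %d metabolites x %d time points x %d individuals x %d diets\n",
              dm[1], dm[2], dm[3], dm[4]))
  if (length(x$preprocessing_log))
    cat("preprocessing:", paste(x$preprocessing_log, collapse = " -> "), "\n")
  invisible(x)
}

tensor_cols <- c("metabolite", "time_index", "individual", "diet", "value")

#' Read a response tensor from long-format delimited text
#'
#' The file must have columns `metabolite,time_index,individual,diet,value`
#' and contain the complete crossing of the four keys.  Axis labels are
#' ordered deterministically (radix-sorted; time numerically) unless an
#' explicit order is supplied.  Reading and then writing with the same dialect
#' reproduces the file byte-for-byte.
#'
#' @param path file path.
#' @param sep field separator (default `,`).
#' @param dec decimal mark.
#' @param metabolite_order,individual_order,diet_order optional explicit axis
#'   orders (must be permutations of the labels present).
#' @return A [response_tensor()].
#' @export
read_tensor_long <- function(path, sep = ",", dec = ".",
                             metabolite_order = NULL, individual_order = NULL,
                             diet_order = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          colClasses = c("character", "numeric", "character",
                                         "character", "numeric"),
                          check.names = FALSE)
  if (!identical(names(df), tensor_cols))
    stopf("expected columns %s, found %s",
          paste(tensor_cols, collapse = ","), paste(names(df), collapse = ","))
  axis_order <- function(vals, explicit, label) {
    u <- unique(vals)
    if (is.null(explicit)) return(radix_sort(u))
    if (!setequal(explicit, u))
      stopf("explicit %s order does not match labels present in file", label)
    as.character(explicit)
  }
  mets <- axis_order(df$metabolite, metabolite_order, "metabolite")
  times <- sort(unique(df$time_index))
  inds <- axis_order(df$individual, individual_order, "individual")
  diets <- axis_order(df$diet, diet_order, "diet")
  M <- length(mets); T_ <- length(times); I <- length(inds); D <- length(diets)
  mi <- match(df$metabolite, mets); ti <- match(df$time_index, times)
  ii <- match(df$individual, inds); di <- match(df$diet, diets)
  lin <- mi + M * ((ti - 1) + T_ * ((ii - 1) + I * (di - 1)))
  if (anyDuplicated(lin)) {
    k <- which(duplicated(lin))[1]
    stopf("duplicate entry for (metabolite=%s, time_index=%s, individual=%s, diet=%s)",
          df$metabolite[k], df$time_index[k], df$individual[k], df$diet[k])
  }
  arr <- array(NA_real_, c(M, T_, I, D))
  arr[lin] <- df$value
  if (anyNA(arr)) {
    miss <- arrayInd(which(is.na(arr)), dim(arr))
    # first absent combination in (metabolite, time, individual, diet) order,
    # metabolite varying slowest
    o <- order(miss[, 1], miss[, 2], miss[, 3], miss[, 4])[1]
    stopf("incomplete tensor: missing combination (metabolite=%s, time_index=%s, individual=%s, diet=%s)",
          mets[miss[o, 1]], times[miss[o, 2]], inds[miss[o, 3]], diets[miss[o, 4]])
  }
  if (any(!is.finite(arr))) stopf("tensor contains non-finite values")
  response_tensor(arr, mets, times, inds, diets)
}

#' Write a response tensor as long-format delimited text
#'
#' Rows are emitted in canonical order (metabolite slowest, then time,
#' individual, diet).  A sidecar JSON (`<path>.json`) records axis labels and
#' the preprocessing log.
#'
#' @param x a [response_tensor()].
#' @param path output file path.
#' @param sep,dec dialect, as in [read_tensor_long()].
#' @param sidecar write the provenance sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_tensor_long <- function(x, path, sep = ",", dec = ".", sidecar = TRUE) {
  stopifnot(inherits(x, "response_tensor"))
  dm <- dim(x)
  g <- expand.grid(diet = seq_len(dm[4]), individual = seq_len(dm[3]),
                   time = seq_len(dm[2]), metabolite = seq_len(dm[1]))
  val <- x$values[cbind(g$metabolite, g$time, g$individual, g$diet)]
  fmt <- function(v) {
    s <- vapply(v, function(z) as.character(z), character(1))
    if (dec != ".") s <- gsub(".", dec, s, fixed = TRUE)
    s
  }
  lines <- c(paste(tensor_cols, collapse = sep),
             paste(x$metabolite_ids[g$metabolite],
                   fmt(x$time_points[g$time]),
                   x$individual_ids[g$individual],
                   x$diet_ids[g$diet],
                   fmt(val), sep = sep))
  writeLines(lines, path)
  if (sidecar) {
    jsonlite::write_json(
      list(metabolite_ids = x$metabolite_ids, time_points = x$time_points,
           individual_ids = x$individual_ids, diet_ids = x$diet_ids,
           preprocessing_log = x$preprocessing_log),
      paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Subtract the pre-meal baseline sample from every time series
#'
#' The first time point of each (metabolite, individual, diet) series is
#' subtracted from the whole series, so analysis focuses on the postprandial
#' deviation and the baseline slice becomes exactly zero.
#'
#' @param x a [response_tensor()] with at least two time points.
#' @return The baseline-subtracted tensor, with a `baseline_subtracted` tag
#'   appended to the preprocessing log.
#' @export
subtract_baseline <- function(x) {
  stopifnot(inherits(x, "response_tensor"))
  if ("baseline_subtracted" %in% x$preprocessing_log)
    stopf("baseline already subtracted")
  if (dim(x)[2] < 2L) stopf("need at least two time points")
  out <- x$values - x$values[, rep(1L, dim(x)[2]), , , drop = FALSE]
  response_tensor(out, x$metabolite_ids, x$time_points, x$individual_ids,
                  x$diet_ids, c(x$preprocessing_log, "baseline_subtracted"))
}

#' Standardize responses per diet to unit variance
#'
#' Each (metabolite, diet) slice is divided by its sample standard deviation
#' pooled over all time points and individuals (`mode = "per_metabolite"`,
#' the default), or each diet slice by one pooled standard deviation over all
#' metabolites as well (`mode = "pooled"`).  The returned scales invert the
#' transform exactly.
#'
#' @param x a [response_tensor()].
#' @param mode pooling scope, `"per_metabolite"` or `"pooled"`.
#' @return A list with `tensor` (standardized) and `scales` (M x D matrix, or
#'   1 x D when pooled).
#' @export
standardize_per_diet <- function(x, mode = c("per_metabolite", "pooled")) {
  stopifnot(inherits(x, "response_tensor"))
  mode <- match.arg(mode)
  if (any(startsWith(x$preprocessing_log, "standardized_per_diet")))
    stopf("responses already standardized per diet")
  dm <- dim(x)
  out <- x$values
  if (mode == "per_metabolite") {
    scales <- matrix(NA_real_, dm[1], dm[4],
                     dimnames = list(x$metabolite_ids, x$diet_ids))
    for (d in seq_len(dm[4])) {
      slab <- matrix(x$values[, , , d], nrow = dm[1])  # M x (T*I)
      scales[, d] <- apply(slab, 1, stats::sd)
    }
    bad <- which(scales <= .Machine$double.eps, arr.ind = TRUE)
    if (nrow(bad)) {
      pairs <- paste0("(", x$metabolite_ids[bad[, 1]], ", ",
                      x$diet_ids[bad[, 2]], ")")
      stopf("zero-variance slice(s): %s; filter before standardizing",
            paste(pairs, collapse = ", "))
    }
    for (d in seq_len(dm[4]))
      out[, , , d] <- x$values[, , , d] / scales[, d]
  } else {
    scales <- matrix(NA_real_, 1, dm[4], dimnames = list(NULL, x$diet_ids))
    for (d in seq_len(dm[4]))
      scales[1, d] <- stats::sd(as.vector(x$values[, , , d]))
    bad <- which(scales <= .Machine$double.eps)
    if (length(bad))
      stopf("zero-variance diet slice(s): %s",
            paste(x$diet_ids[bad], collapse = ", "))
    for (d in seq_len(dm[4]))
      out[, , , d] <- x$values[, , , d] / scales[1, d]
  }
  tens <- response_tensor(out, x$metabolite_ids, x$time_points,
                          x$individual_ids, x$diet_ids,
                          c(x$preprocessing_log,
                            paste0("standardized_per_diet:mode=", mode)))
  list(tensor = tens, scales = scales)
}

#' Invert a per-diet standardization
#'
#' @param x a standardized [response_tensor()].
#' @param scales the scales returned by [standardize_per_diet()].
#' @return The tensor in original units, with the standardization tag removed.
#' @export
invert_standardization <- function(x, scales) {
  stopifnot(inherits(x, "response_tensor"))
  tag <- grep("^standardized_per_diet", x$preprocessing_log)
  if (!length(tag)) stopf("tensor is not standardized")
  dm <- dim(x)
  out <- x$values
  for (d in seq_len(dm[4])) {
    s <- if (nrow(scales) == 1L) rep(scales[1, d], dm[1]) else scales[, d]
    out[, , , d] <- x$values[, , , d] * s
  }
  response_tensor(out, x$metabolite_ids, x$time_points, x$individual_ids,
                  x$diet_ids, x$preprocessing_log[-tag[length(tag)]])
}

#' Exclude metabolites with near-constant trajectories
#'
#' A metabolite is kept when at least one of its (individual, diet) time
#' series has a standard deviation over time of at least `threshold`
#' (concentration units, e.g. 1e-3 mM).  Apply before standardization.
#'
#' @param x a [response_tensor()].
#' @param threshold positive standard-deviation cutoff.
#' @return The filtered tensor (metabolite order preserved).
#' @export
filter_low_variance <- function(x, threshold) {
  stopifnot(inherits(x, "response_tensor"))
  if (!is.numeric(threshold) || threshold <= 0)
    stopf("`threshold` must be positive")
  sds <- apply(x$values, c(1, 3, 4), stats::sd)      # M x I x D
  keep <- apply(matrix(sds, nrow = dim(x)[1]), 1, max) >= threshold
  if (!any(keep)) stopf("all metabolites removed at threshold %g", threshold)
  response_tensor(x$values[keep, , , , drop = FALSE],
                  x$metabolite_ids[keep], x$time_points, x$individual_ids,
                  x$diet_ids,
                  c(x$preprocessing_log,
                    paste0("filter_low_variance:threshold=", num_tag(threshold))))
}

# Deterministic endpoint-inclusive log-spaced index grid on 1..T with
# round-to-integer and duplicate resolution by advancing to the next unused
# index (capped so the tail always fits).
log_indices <- function(T_, n_out) {
  raw <- exp(seq(0, log(T_), length.out = n_out))
  idx <- round(raw)
  prev <- 0L
  for (k in seq_len(n_out)) {
    v <- max(idx[k], prev + 1L)
    v <- min(v, T_ - (n_out - k))
    idx[k] <- v
    prev <- v
  }
  as.integer(idx)
}

#' Logarithmic down-sampling of the time axis
#'
#' Selects `n_out` time indices spaced logarithmically between the first and
#' last available index (both always included), rounded to the integer grid
#' with duplicates resolved by advancing to the next unused index.  Used to
#' reduce densely sampled simulations (e.g. 60 points at 10-min intervals) to
#' the measured design of eight points.
#'
#' @param x a [response_tensor()].
#' @param n_out number of time points to keep, `2 <= n_out <= T`.
#' @return The down-sampled tensor.
#' @export
downsample_logarithmic <- function(x, n_out) {
  stopifnot(inherits(x, "response_tensor"))
  T_ <- dim(x)[2]
  if (n_out < 2 || n_out > T_)
    stopf("`n_out` must be between 2 and T = %d", T_)
  idx <- log_indices(T_, as.integer(n_out))
  response_tensor(x$values[, idx, , , drop = FALSE], x$metabolite_ids,
                  x$time_points[idx], x$individual_ids, x$diet_ids,
                  c(x$preprocessing_log,
                    paste0("downsample_logarithmic:n_out=", as.integer(n_out))))
}

#' Replay a preprocessing log on raw data
#'
#' Applies the transform sequence recorded in a `preprocessing_log` to a raw
#' tensor, reproducing the processed tensor bit-for-bit.
#'
#' @param x a raw [response_tensor()].
#' @param log character vector of preprocessing tags.
#' @return The processed tensor.
#' @export
replay_preprocessing <- function(x, log) {
  for (tag in log) {
    parts <- strsplit(tag, ":", fixed = TRUE)[[1]]
    op <- parts[1]
    arg <- if (length(parts) > 1) sub("^[^=]*=", "", parts[2]) else NULL
    x <- switch(op,
      baseline_subtracted = subtract_baseline(x),
      standardized_per_diet = standardize_per_diet(x, mode = arg)$tensor,
      filter_low_variance = filter_low_variance(x, as.numeric(arg)),
      downsample_logarithmic = downsample_logarithmic(x, as.integer(arg)),
      stopf("unknown preprocessing tag: %s", tag))
  }
  x
}

#' Diet input matrix (impulse magnitudes per diet)
#'
#' Holds the per-diet input vectors: one column per diet, one row per input
#' feature (e.g. fat, protein, carbohydrate in grams).
#'
#' @param inputs numeric l x D matrix.
#' @param input_names,diet_ids axis labels.
#' @return An object of class `diet_input_matrix`.
#' @export
diet_input_matrix <- function(inputs, input_names = NULL, diet_ids = NULL) {
  inputs <- as.matrix(inputs)
  if (any(!is.finite(inputs))) stopf("diet inputs must be finite")
  input_names <- as.character(input_names %||% rownames(inputs) %||%
                                paste0("input", seq_len(nrow(inputs))))
  diet_ids <- as.character(diet_ids %||% colnames(inputs) %||%
                             paste0("d", seq_len(ncol(inputs))))
  stopifnot(length(input_names) == nrow(inputs),
            length(diet_ids) == ncol(inputs))
  dimnames(inputs) <- list(input_names, diet_ids)
  structure(list(inputs = inputs, input_names = input_names,
                 diet_ids = diet_ids),
            class = "diet_input_matrix")
}

#' @export
print.diet_input_matrix <- function(x, ...) {
  cat(sprintf("<diet_input_matrix> %d inputs x %d diets\n",
              nrow(x$inputs), ncol(x$inputs)))
  print(x$inputs)
  invisible(x)
}

#' Macronutrient composition of the three intervention diets
#'
#' Fat, protein and carbohydrate content (grams) of the baked herring, pickled
#' herring and baked beef meals from the crossover intervention design, usable
#' as the default three-input diet matrix.
#'
#' @return A [diet_input_matrix()] (3 inputs x 3 diets).
#' @export
intervention_diets <- function() {
  m <- cbind(baked_herring = c(29, 33, 47),
             pickled_herring = c(29, 29, 81),
             baked_beef = c(35, 43, 47))
  rownames(m) <- c("fat", "protein", "carbohydrate")
  diet_input_matrix(m)
}

#' Read/write a diet input matrix (wide CSV, first column = input name)
#' @param path file path.
#' @rdname diet_io
#' @export
read_diet_inputs <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  diet_input_matrix(as.matrix(df[, -1, drop = FALSE]),
                    input_names = df[[1]], diet_ids = names(df)[-1])
}

#' @param x a [diet_input_matrix()].
#' @rdname diet_io
#' @export
write_diet_inputs <- function(x, path) {
  df <- data.frame(input = x$input_names, x$inputs, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Clinical baseline table
#'
#' Per-individual clinical and anthropometric baseline measures (e.g.
#' creatinine, BMI).  Missing values are permitted but flagged.
#'
#' @param measures numeric I x C matrix.
#' @param measure_names,individual_ids axis labels.
#' @return An object of class `clinical_table`.
#' @export
clinical_table <- function(measures, measure_names = NULL,
                           individual_ids = NULL) {
  measures <- as.matrix(measures)
  measure_names <- as.character(measure_names %||% colnames(measures) %||%
                                  paste0("measure", seq_len(ncol(measures))))
  individual_ids <- as.character(individual_ids %||% rownames(measures) %||%
                                   paste0("i", seq_len(nrow(measures))))
  stopifnot(length(measure_names) == ncol(measures),
            length(individual_ids) == nrow(measures))
  dimnames(measures) <- list(individual_ids, measure_names)
  structure(list(measures = measures, measure_names = measure_names,
                 individual_ids = individual_ids,
                 has_missing = anyNA(measures)),
            class = "clinical_table")
}

#' Read a clinical table from CSV (first column = individual id)
#' @param path file path.
#' @return A [clinical_table()].
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  clinical_table(as.matrix(df[, -1, drop = FALSE]),
                 measure_names = names(df)[-1], individual_ids = df[[1]])
}
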