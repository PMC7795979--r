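#' Build a feature table from labelled frames
#'
#' Runs every frame through the preprocessing chain (grayscale, Kirsch
#' edges, centred crop) and GLCM descriptor extraction, yielding one
#' training case per frame in input order. Cases whose correlation
#' descriptor is undefined (zero marginal variance — a constant crop) are
#' dropped with a warning: they carry no texture signal.
#'
#' @param frames either the list returned by [generate_dataset()] (elements
#'   with `image`, `class`, `speed`), a list of images, or a character
#'   vector of image file paths.
#' @param labels,speeds class labels and transport speeds per frame;
#'   required unless `frames` carries them.
#' @param name optional set identifier (e.g. "Z1") stored as an attribute.
#' @param kirsch_size,crop_region passed to [preprocess_frame()].
#' @param levels,distance,angles,symmetric passed to [extract_features()].
#' @return A `feature_table`: a data.frame with columns `asm`, `entropy`,
#'   `contrast`, `correlation`, `idm`, `label`, `speed`.
#' @export
build_table <- function(frames, labels = NULL, speeds = NULL, name = NULL,
                        kirsch_size = 5L, crop_region = NULL,
                        levels = 8L, distance = 1L,
                        angles = c(0, 45, 90, 135), symmetric = TRUE) {
  if (is.list(frames) && length(frames) > 0L &&
      is.list(frames[[1]]) && !is.null(frames[[1]]$image)) {
    labels <- vapply(frames, `[[`, character(1), "class")
    speeds <- vapply(frames, `[[`, numeric(1), "speed")
    frames <- lapply(frames, `[[`, "image")
  }
  n <- length(frames)
  if (n == 0L) {
    return(new_feature_table(empty_feature_rows(), name))
  }
  if (length(labels) != n || length(speeds) != n) {
    stop("labels and speeds must match the number of frames", call. = FALSE)
  }
  for (l in labels) assert_seed_class(l)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    if (is.character(fr)) {
      if (!file.exists(fr)) {
        stop("cannot read frame: ", fr, call. = FALSE)
      }
      fr <- read_image(fr)
    }
    edge <- preprocess_frame(fr, kirsch_size = kirsch_size,
                             crop_region = crop_region)
    fv <- extract_features(edge, levels = levels, distance = distance,
                           angles = angles, symmetric = symmetric)
    rows[[i]] <- data.frame(t(fv), label = labels[i], speed = speeds[i])
  }
  tab <- do.call(rbind, rows)
  bad <- is.na(tab$correlation)
  if (any(bad)) {
    warning(sum(bad), " case(s) dropped: undefined correlation descriptor",
            call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  rownames(tab) <- NULL
  new_feature_table(tab, name)
}

empty_feature_rows <- function() {
  data.frame(asm = numeric(), entropy = numeric(), contrast = numeric(),
             correlation = numeric(), idm = numeric(),
             label = character(), speed = numeric())
}

new_feature_table <- function(df, name = NULL) {
  structure(df, name = name, class = c("feature_table", "data.frame"))
}

feature_names <- function() c("asm", "entropy", "contrast", "correlation", "idm")

assert_feature_table <- function(tab) {
  if (!is.data.frame(tab) ||
      !all(c(feature_names(), "label") %in% names(tab))) {
    stop("expected a feature table with descriptor and label columns",
         call. = FALSE)
  }
  tab
}

#' Stratified 2:1:1 train/validation/test split
#'
#' Within each class the cases are shuffled with `rng_seed` and allocated to
#' the three subsets at a 2:1:1 ratio. When a class size is not divisible by
#' 4 the remainder is assigned one case at a time in the order train,
#' validation, test. The split is deterministic for a fixed seed; the three
#' subsets are disjoint and their union is the input table.
#'
#' @param table a `feature_table` from [build_table()].
#' @param rng_seed integer seed for the per-class shuffles.
#' @return A `split_table`: list with elements `train`, `validation`,
#'   `test` (feature tables), `ratio = c(2, 1, 1)` and `rng_seed`.
#' @export
split_2_1_1 <- function(table, rng_seed) {
  assert_feature_table(table)
  if (nrow(table) < 4L) stop("need at least 4 cases to split", call. = FALSE)
  classes <- unique(table$label)
  sizes <- table(table$label)
  if (any(sizes < 4L)) {
    stop("every class needs at least 4 cases; too few in: ",
         paste(names(sizes)[sizes < 4L], collapse = ", "), call. = FALSE)
  }
  grp <- character(nrow(table))
  with_rng(rng_seed, {
    for (cl in classes) {
      idx <- sample(which(table$label == cl))
      n <- length(idx)
      q <- n %/% 4L
      r <- n %% 4L
      n_train <- 2L * q + (r >= 1L)
      n_val <- q + (r >= 2L)
      grp[idx[seq_len(n_train)]] <- "train"
      grp[idx[n_train + seq_len(n_val)]] <- "validation"
      grp[idx[(n_train + n_val + 1L):n]] <- "test"
    }
  })
  nm <- attr(table, "name")
  structure(list(
    train = new_feature_table(table[grp == "train", , drop = FALSE], nm),
    validation = new_feature_table(table[grp == "validation", , drop = FALSE], nm),
    test = new_feature_table(table[grp == "test", , drop = FALSE], nm),
    ratio = c(2L, 1L, 1L), rng_seed = as.integer(rng_seed)),
    class = "split_table")
}

#' Read/write feature tables as CSV
#'
#' A `split_table` is serialised with an extra `subset` column; a plain
#' `feature_table` without one.
#'
#' @param x a `feature_table` or `split_table`.
#' @param path CSV path.
#' @return `path` invisibly for writing; the table or split for reading.
#' @export
write_feature_csv <- function(x, path) {
  if (inherits(x, "split_table")) {
    parts <- lapply(c("train", "validation", "test"), function(s) {
      df <- as.data.frame(x[[s]])
      if (nrow(df) > 0L) df$subset <- s else df$subset <- character()
      df
    })
    df <- do.call(rbind, parts)
  } else {
    df <- as.data.frame(assert_feature_table(x))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("subset" %in% names(df)) {
    parts <- lapply(c("train", "validation", "test"), function(s) {
      new_feature_table(df[df$subset == s, setdiff(names(df), "subset"),
                           drop = FALSE])
    })
    structure(list(train = parts[[1]], validation = parts[[2]],
                   test = parts[[3]], ratio = c(2L, 1L, 1L),
                   rng_seed = NA_integer_),
              class = "split_table")
  } else {
    new_feature_table(df)
  }
}
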