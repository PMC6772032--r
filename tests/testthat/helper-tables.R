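# Published reference tables, frozen as fixtures.

# Symmetric case, n = 16, times representation: exact integers, rows c = 0..15,
# columns l = 1..16; entries are 2^15 * P16(C = c, L = l).
table1_n16 <- function() {
  m <- matrix(c(
    0,   0,    0,    0,    0,   0,   0,   0,   0,  0,  0,  0, 0, 0, 0, 1,
    0,   0,    0,    0,    0,   0,   0,   1,   2,  2,  2,  2, 2, 2, 2, 0,
    0,   0,    0,    0,    0,   6,  15,  21,  18, 15, 12,  9, 6, 3, 0, 0,
    0,   0,    0,    1,   34,  90, 106,  84,  60, 40, 24, 12, 4, 0, 0, 0,
    0,   0,    0,   65,  300, 370, 280, 175, 100, 50, 20,  5, 0, 0, 0, 0,
    0,   0,   21,  525,  960, 741, 420, 210,  90, 30,  6,  0, 0, 0, 0, 0,
    0,   0,  266, 1652, 1617, 882, 392, 147,  42,  7,  0,  0, 0, 0, 0, 0,
    0,   1, 1106, 2716, 1652, 672, 224,  56,   8,  0,  0,  0, 0, 0, 0, 0,
    0,  36, 2268, 2646, 1080, 324,  72,   9,   0,  0,  0,  0, 0, 0, 0, 0,
    0, 210, 2640, 1605,  450,  90,  10,   0,   0,  0,  0,  0, 0, 0, 0, 0,
    0, 462, 1815,  605,  110,  11,   0,   0,   0,  0,  0,  0, 0, 0, 0, 0,
    0, 495,  726,  132,   12,   0,   0,   0,   0,  0,  0,  0, 0, 0, 0, 0,
    0, 286,  156,   13,    0,   0,   0,   0,   0,  0,  0,  0, 0, 0, 0, 0,
    0,  91,   14,    0,    0,   0,   0,   0,   0,  0,  0,  0, 0, 0, 0, 0,
    0,  15,    0,    0,    0,   0,   0,   0,   0,  0,  0,  0, 0, 0, 0, 0,
    1,   0,    0,    0,    0,   0,   0,   0,   0,  0,  0,  0, 0, 0, 0, 0),
    nrow = 16, byrow = TRUE)
  dimnames(m) <- list(paste0("c=", 0:15), paste0("l=", 1:16))
  m
}

# p = 0.6, n = 16, times representation, shown with one decimal digit.
table2_n16_p06 <- function() {
  m <- matrix(c(
    "0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","9.3",
    "0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.7","1.6","1.9","2.6","3.8","5.6","8.3","12.4","0.0",
    "0.0","0.0","0.0","0.0","0.0","7.5","22.8","41.2","39.3","37.5","35.3","31.9","26.2","16.5","0.0","0.0",
    "0.0","0.0","0.0","0.7","28.0","88.6","130.0","121.0","102.2","82.8","61.6","38.9","16.6","0.0","0.0","0.0",
    "0.0","0.0","0.0","63.4","337.8","485.0","423.3","302.3","202.2","120.6","58.5","18.0","0.0","0.0","0.0","0.0",
    "0.0","0.0","15.9","451.3","947.6","845.0","550.2","323.0","166.1","67.6","16.7","0.0","0.0","0.0","0.0","0.0",
    "0.0","0.0","234.2","1619.3","1784.1","1098.1","557.9","245.0","83.5","16.8","0.0","0.0","0.0","0.0","0.0","0.0",
    "0.0","0.7","900.4","2439.2","1660.7","764.3","295.9","87.9","15.2","0.0","0.0","0.0","0.0","0.0","0.0","0.0",
    "0.0","28.7","1977.6","2518.8","1138.4","386.4","99.8","14.8","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0",
    "0.0","160.0","2159.1","1427.7","444.0","101.6","13.2","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0",
    "0.0","369.8","1535.6","553.4","111.8","12.8","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0",
    "0.0","379.0","582.9","114.6","11.7","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0",
    "0.0","223.9","127.4","11.5","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0",
    "0.0","68.2","10.9","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0",
    "0.0","11.3","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0",
    "0.7","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0","0.0"),
    nrow = 16, byrow = TRUE)
  dimnames(m) <- list(paste0("c=", 0:15), paste0("l=", 1:16))
  m
}

# Anhoej-rule specificities for n = 10..100 (published at three decimals,
# laid out as tens + ones; here in long format ordered by n).
table3_specificities <- function() {
  byTens <- list(
    `10` = c(0.955, 0.951, 0.957, 0.963, 0.939, 0.949, 0.953, 0.935, 0.941, 0.921),
    `20` = c(0.929, 0.933, 0.917, 0.952, 0.934, 0.944, 0.950, 0.936, 0.943, 0.928),
    `30` = c(0.936, 0.920, 0.929, 0.935, 0.922, 0.929, 0.915, 0.922, 0.908, 0.916),
    `40` = c(0.921, 0.910, 0.915, 0.903, 0.910, 0.897, 0.936, 0.943, 0.932, 0.939),
    `50` = c(0.927, 0.935, 0.923, 0.931, 0.918, 0.927, 0.933, 0.923, 0.929, 0.919),
    `60` = c(0.926, 0.915, 0.922, 0.911, 0.919, 0.924, 0.915, 0.921, 0.911, 0.918),
    `70` = c(0.908, 0.914, 0.904, 0.911, 0.916, 0.908, 0.913, 0.904, 0.910, 0.901),
    `80` = c(0.907, 0.898, 0.904, 0.894, 0.901, 0.906, 0.898, 0.903, 0.894, 0.900),
    `90` = c(0.891, 0.931, 0.922, 0.929, 0.920, 0.927, 0.933, 0.925, 0.931, 0.922),
    `100` = 0.929)
  n <- unlist(lapply(names(byTens), function(t) {
    as.integer(t) + seq_along(byTens[[t]]) - 1L
  }))
  data.frame(n = n, specificity = unname(unlist(byTens)))
}

# random exact probability vectors over denominator 10, for oracle checks
random_prob_vector <- function(n) {
  probabilityVector(sprintf("%d/10", sample(1:9, n, replace = TRUE)))
}
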