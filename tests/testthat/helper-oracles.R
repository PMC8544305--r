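# Brute-force per-window CGI statistics: the independent oracle for island
# detection. Deliberately written as an explicit per-window loop, separate
# from the vectorised implementation it checks.
brute_cgi_windows <- function(chars, window = 100) {
  len <- length(chars)
  t(vapply(seq_len(len - window + 1), function(i) {
    w <- chars[i:(i + window - 1)]
    nc <- sum(w == "C"); ng <- sum(w == "G")
    ncg <- sum(w[-window] == "C" & w[-1] == "G")
    hasN <- any(!w %in% c("A", "C", "G", "T"))
    exp <- nc * ng / window
    c(gc = 100 * (nc + ng) / window,
      obs_exp = if (exp > 0) ncg / exp else 0,
      pass = !hasN && 100 * (nc + ng) / window >= 50 &&
        (if (exp > 0) ncg / exp else 0) >= 0.6)
  }, numeric(3)))
}

brute_cgi <- function(chars, window = 100, min_length = 200) {
  st <- brute_cgi_windows(chars, window)
  pass <- which(st[, "pass"] == 1)
  if (length(pass) == 0) return(NULL)
  runs <- split(pass, cumsum(c(1, diff(pass) > window)))
  out <- lapply(runs, function(r) {
    s <- min(r); e <- max(r) + window - 1
    if (e - s + 1 < min_length) return(NULL)
    data.frame(start = s, end = e,
               gc = mean(st[r, "gc"]), obs_exp = mean(st[r, "obs_exp"]))
  })
  do.call(rbind, out)
}
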