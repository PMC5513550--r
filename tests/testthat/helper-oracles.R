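# Independent week-by-week oracle for the stress-accumulation rule:
# walk backwards from each week (wrapping across the year boundary) to
# count the consecutive stressed run; a condition holding all year has
# no wrap and counts from the start of the year.
oracle_accumulate <- function(exceed, rate) {
  n <- length(exceed)
  total <- 0
  for (w in seq_len(n)) {
    if (exceed[w] <= 0) next
    k <- 0
    i <- w
    while (exceed[i] > 0 && k < n) {
      k <- k + 1
      i <- if (i == 1) n else i - 1
    }
    if (k == n) k <- w
    total <- total + abs(rate) * exceed[w] * k
  }
  100 * min(1, total)
}
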