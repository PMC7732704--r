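# Scoring key for the in-app FFMQ-SF: 19 items over 4 subscales
# (the describing subscale is not administered).  Responses are on a
# 1-5 Likert scale; reverse-scored items map r -> 6 - r before summing.
# Item ids are this package's labels; swap in your own key file if your
# deployment logs different ids or a different reverse set.
scale_min: 1
scale_max: 5
subscales:
  observing: [obs1, obs2, obs3, obs4]
  acting_with_awareness: [aa1, aa2, aa3, aa4, aa5]
  nonjudging: [nj1, nj2, nj3, nj4, nj5]
  nonreactivity: [nr1, nr2, nr3, nr4, nr5]
reverse_scored: [aa1, aa2, aa3, aa4, aa5, nj1, nj2, nj3, nj4, nj5]
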