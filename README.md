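# arrivalwatch

Syndromic-style surveillance of species **arrival events** in a social-media
text stream.

Biosecurity surveillance wants early warning that an organism has turned up
in a region. Posts by the general public are a tempting indirect signal: when
Bogong moths (*Agrotis infusa*) swarm into Canberra each Spring, or the
Eastern Koel (*Eudynamys orientalis*) starts calling at dawn, people write
about it. `arrivalwatch` packages the full analysis chain needed to test how
far that signal can be trusted:

1. **Queries.** Boolean keyword queries over tweet text, in three styles:
   *taxonomic* (`"agrotis infusa"`), *common name*
   (`(bogong OR bogan) AND moth`) and *symptomatic* — descriptive words that
   indicate presence without naming the species. Symptomatic vocabulary is
   mined from a seed corpus: lowercase → strip numbers and punctuation →
   tokenize → drop stopwords → Snowball-stem, then keep terms occurring at
   least 5 times.
2. **Query quality.** The signal-to-noise ratio of a query is the fraction
   of its hits judged relevant, `SNR = r / h`. Result sets too large to
   label are subsampled with month-stratified random sampling and the SNR
   estimated from the labelled subsample.
3. **Detection.** Weekly hit counts are prewhitened with an autoregressive
   model (order read off the PACF, conditional least-squares fit, residual
   independence checked by Ljung–Box), and the standardised residuals
   `z_t = e_t / σ̂` feed a two-sided tabular CUSUM

   ```
   C+_t = max(0, C+_{t-1} + z_t − k)      alarm when C+_t > h   (UDB)
   C−_t = min(0, C−_{t-1} + z_t + k)      alarm when C−_t < −h  (LDB)
   ```

   with defaults `k = 0.5`, `h = 5`. An upper alarm during the Spring window
   (September–November) counts as detecting that season's arrival.
4. **Validation.** Ground-truth helpers turn field surveys of moth patch
   volumes (width × height × depth per patch) into percent-of-total-volume
   series, and historical monthly bird counts into a 12-month sighting
   profile; `evaluate_detections()` scores detections, delays and
   out-of-season false alarms against them.
5. **Synthetic streams.** A generator produces tweet streams with the
   structure the analysis assumes — autocorrelated overdispersed background
   chatter, an arrival-only pulse of relevant posts, optional out-of-season
   confounder bursts sharing query vocabulary — with the realized SNR
   calibrated to a target, so the whole pipeline runs and is tested without
   any data download.

## Worked example

Simulate two seasons of a well-known species (arrivals 7 Sep 2013 and
12 Sep 2014), run a common-name query, and detect the arrivals:

```r
library(arrivalwatch)

period <- coverage_period("2013-07-01", "2015-05-31")
cfg <- stream_config(period, arrival_dates = c("2013-09-07", "2014-09-12"),
                     target_snr = 0.9, seed = 42)
stream <- generate_stream(cfg)

q <- parse_query("bogong AND moth", type = "common_name")
hits <- run_query(q, stream)
estimate_snr(hits)
#> SNR: 200/220 = 91% (approximate, from subsample)

det <- detect_arrivals(hits, period = period)
det
#> Arrival detection: 100 weeks (fitted 1..100), AR order 2
#>   residuals independent: TRUE (Ljung-Box p = 0.946)
#>   events:
#>     2013-09-09 upper
#>     2013-09-23 upper
#>     2013-09-30 upper
#>     2014-09-15 upper

evaluate_detections(det$events, spring_windows(period),
                    arrival_dates = c("2013-09-07", "2014-09-12"))
#> Season detection:
#>  year detected first_detection_week delay_days
#>  2013     TRUE           2013-09-09          2
#>  2014     TRUE           2014-09-15          3
#> Out-of-season upper alarms: 0
```

The query recovered 220 hits of which 200 were relevant (91% SNR — the
stream was calibrated to 90%). The CUSUM chart of the AR(2)-prewhitened
weekly counts crossed the upper decision bound in the week of each true
arrival, giving detection delays of 2 and 3 days and no false alarms. The
same pipeline run on a low-SNR symptomatic-style stream (see
`contrast_experiment()`) detects almost nothing in season and raises
out-of-season alarms on confounder bursts — the quality of the query, not
the chart, is the binding constraint.

## Package tour

| area | functions |
| --- | --- |
| tweet store | `tweet_records`, `read_tweets`, `write_tweets`, `filter_period`, `coverage_period` |
| queries | `parse_query`, `deparse_query`, `match_query`, `run_query`, `read_queries` |
| term mining | `preprocess_text`, `term_frequencies`, `frequent_terms`, `build_symptomatic_query`, `stem_words` |
| relevance | `compute_snr`, `stratified_sample`, `estimate_snr`, `verifiability_summary` |
| surveillance | `weekly_counts`, `acf_values`, `pacf_values`, `select_order`, `fit_ar`, `diagnose_fit`, `standardize_residuals`, `cusum`, `detect_events`, `detect_arrivals` |
| validation | `percent_volume`, `monthly_profile`, `spring_windows`, `evaluate_detections` |
| synthetic data | `stream_config`, `generate_stream`, `truth_config`, `generate_truth`, `generate_ar`, `inject_shift`, `contrast_experiment` |

The methods vignette (`vignettes/arrival-detection.Rmd`) documents the
models, the tunable parameters and the design decisions in detail.
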