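# Bundled data files

## knight_clock_synthetic.csv, bohlin_clock_synthetic.csv

SYNTHETIC stand-ins for the two published cord-blood gestational-age clock
coefficient tables the pipeline targets. They reproduce the published clocks'
*dimensions and unit conventions* — 148 CpG terms reported in weeks
("knight"), 96 CpG terms reported in days ("bohlin"), one `(Intercept)` row —
but the CpG identifiers and coefficient values are simulated (fixed-seed
draws; magnitudes bounded so that any target age in the plausible gestational
range is reachable with beta values inside [0, 1]). They exist so the
generator, clock-prediction and acceptance machinery can run self-contained;
they carry no biological information and must not be used for inference on
real arrays. To analyse real data, supply the published coefficient tables via
`read_clock_csv()`.

Format: `cpg_id,coefficient`; the intercept is the row with the reserved id
`(Intercept)`.

## file_schemas.csv

Column-by-column schema of every CSV the pipeline reads or writes.
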