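information layer file, CSV dialect
===================================

One row per point, one column per information layer; each cell is the
integer class of that point in that layer, comma-separated. The dialect
cannot express layer names, class labels or a declared class count: the
reader infers each column's class count as its number of distinct
values, and writing any of those fields to CSV emits LOSSY_CSV warnings
(sparse class numberings are renumbered to a contiguous 0-based range so
the emitted text re-parses).

Grammar (EBNF):

  file    = row , { newline , row } , [ newline ] ;
  row     = integer , { "," , integer } ;
  integer = [ ws ] , [ "-" ] , digit , { digit } , [ ws ] ;
  newline = LF | CRLF ;
  ws      = { " " | TAB } ;

Notes
-----
- all rows must have the same number of columns (else RAGGED_LAYERS)
- rows are in the same order as the dataset's points
- blank trailing lines are ignored
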