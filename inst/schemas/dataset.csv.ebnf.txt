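dataset file, CSV dialect
=========================

One point per line; exactly three comma-separated numeric fields per
line. The dialect cannot express a dataset name or the chain flag: a CSV
parse always yields the default name "dataset" and chain = false, and
writing a named or chained dataset to CSV emits LOSSY_CSV warnings.

Grammar (EBNF):

  file     = line , { newline , line } , [ newline ] ;
  line     = number , "," , number , "," , number ;
  number   = [ ws ] , [ sign ] , digits , [ "." , digits ] , [ exponent ] , [ ws ] ;
  exponent = ( "e" | "E" ) , [ sign ] , digits ;
  sign     = "+" | "-" ;
  digits   = digit , { digit } ;
  newline  = LF | CRLF ;
  ws       = { " " | TAB } ;

Notes
-----
- separator is the comma only; no quoting, no header row
- leading/trailing whitespace around a field is trimmed
- decimal separator is "."; values must be finite
- blank trailing lines are ignored
- a line with other than three fields is a BAD_ARITY error
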