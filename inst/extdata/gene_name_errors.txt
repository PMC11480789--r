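# Default gene-name-error blocklist: symbol forms known to arise from
# spreadsheet date/format conversion rather than genuine model predictions.
# One token per line; user-overridable via load_lexicon(error_list_path=).
SEPT1
SEPT2
SEPT3
SEPT4
SEPT5
SEPT6
SEPT7
SEPT8
SEPT9
SEPT10
SEPT11
SEPT12
SEPT13
SEPT14
SEPT15
MARCH1
MARCH2
MARCH3
MARCH4
MARCH5
MARCH6
MARCH7
MARCH8
MARCH9
MARCH10
MARCH11
MARC1
MARC2
MAR1
MAR2
MAR3
MAR4
MAR5
MAR6
MAR7
MAR8
MAR9
MAR10
MAR11
DEC1
DEC2
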