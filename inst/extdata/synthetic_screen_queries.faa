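>q_active_dap
MKALIVHHTAGEDCYSWWRVNNGQPLSTTRCGHYDLIGNGISAKGRWPEVTYHAGSNKDL
>q_inactive
MKALIVHHTAGEDCFSWWRVNNGQPLSTTRCGHYDLIGNGISAKGRWPEVTYHAGSNKDL
>q_groove_other
MKALIVHHTAGEDCYSWWEVNNGQPLSTTRCGHYDLIGNGISAKGRWPEVTYHAGSNKDL
>q_indeterminate
MKALIVHHTAGEDCYSWWRVNNGQPLSTTRCGLIGNGISAKGRWPEVTYHAGSNKDL
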