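"symbol","class","length","length_partner","place","manner"
"a","vowel","short","a:",,
"a:","vowel","long","a",,
"p","consonant",,,"labial","stop"
"t","consonant",,,"apical","stop"
"d","consonant",,,"apical","voiced"
"k","consonant",,,"velar","stop"
"g","consonant",,,"velar","voiced"
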