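<?xml version="1.0" encoding="UTF-8"?>
<!-- Standard orientation table (link 202).  Captured atom rows are
     assembled into a molecule node with a concise formula. -->
<template id="l202.orientation" pattern="\s*Standard orientation:\s*"
          section="initialization" molecule="true">
  <record id="atomrow">\s*{1I, g:center}\s+{1I, g:atomicnum}\s+{1I, g:atype}\s+{3F, g:xyz}\s*</record>
  <record id="rule">\s*-{10,}\s*</record>
  <record id="head1">\s*Center\s+Atomic\s+Atomic\s+Coordinates.*</record>
  <record id="head2">\s*Number\s+Number\s+Type\s+X\s+Y\s+Z\s*</record>
</template>
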