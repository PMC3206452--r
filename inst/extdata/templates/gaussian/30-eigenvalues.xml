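<?xml version="1.0" encoding="UTF-8"?>
<!-- Parses the link-601 orbital eigenvalue block.  The template claims a
     chunk of consecutive eigenvalue lines; every line is parsed by a single
     record whose trailing float run is captured into an array named by the
     leading string.  (The beta-eigenvalue branch is omitted here; the same
     record already captures Beta lines under their own labels.) -->
<template id="l601.alphabetaeigen" pattern="\s*(Alpha|Beta)\s+(occ|virt)\. eigenvalues.*"
          repeat="*" endPattern="\s[^A][^B].*" section="calculation">

  <!-- an example of input which also acts as a unit test -->
  <comment class="example.input" id="l601.alphabeta">
Alpha occ. eigenvalues -- -10.17514 -0.68437 -0.38581 -0.38581 -0.38581
Alpha virt. eigenvalues -- 0.11292 0.17036 0.17036 0.17036 0.53917
Alpha virt. eigenvalues -- 0.53917 0.53917 0.88316 0.88316 0.88316
Alpha virt. eigenvalues -- 0.91927 1.09380 1.66027 1.66027 2.21731
Alpha virt. eigenvalues -- 2.21731 2.21731 4.16488
  </comment>

  <!-- all lines are parsed with a single record; the trailing part of the
       line is captured into an array and named with the leading string -->
  <record id="eigen" repeat="*">\s*{X, g:name}\s*eigenvalues \-\-{1_5F, g:eigen}</record>

  <!-- rename the label to conform to the dictionary -->
  <transform process="addDictRef" xpath=".//cml:array[@cmlx:temp='Alpha occ.']" value="cc:alphaocc"/>
  <transform process="addDictRef" xpath=".//cml:array[@cmlx:temp='Alpha virt.']" value="cc:alphavirt"/>
  <!-- stitch lines together -->
  <transform process="joinArrays" xpath=".//cml:array[@dictRef='g:alphaocc']"/>
  <transform process="joinArrays" xpath=".//cml:array[@dictRef='g:alphavirt']"/>

  <!-- expected output (also used for unit testing) -->
  <comment class="example.output" id="l601.alphabeta">
    <module cmlx:templateRef="l601.alphabetaeigen" xmlns="http://www.xml-cml.org/schema" xmlns:cmlx="http://www.xml-cml.org/schema/cmlx">
      <array dataType="xsd:double" size="5" dictRef="cc:alphaocc">-10.17514 -0.68437 -0.38581 -0.38581 -0.38581</array>
      <array dataType="xsd:double" size="18" dictRef="cc:alphavirt">
        0.11292 0.17036 0.17036 0.17036 0.53917 0.53917 0.53917 0.88316 0.88316
        0.88316 0.91927 1.0938 1.66027 1.66027 2.21731 2.21731 2.21731 4.16488</array>
    </module>
  </comment>
</template>
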